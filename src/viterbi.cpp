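#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Two-state Viterbi over marker observations.  States 1/2 = hap1/hap2.
// Uniform initial distribution; symmetric per-observation transition matrix;
// emission log-likelihood is weight * log(1-p_error) when the marker source
// agrees with the state and weight * log(p_error) otherwise.  Ties are broken
// toward staying in the previous state (conservative switch counting).

// [[Rcpp::export]]
IntegerVector cpp_viterbi2(IntegerVector source, NumericVector weight,
                           double p_switch, double p_error) {
    int n = source.size();
    IntegerVector path(n);
    if (n == 0) return path;
    double lsw = std::log(p_switch), lst = std::log1p(-p_switch);
    double lerr = std::log(p_error), lok = std::log1p(-p_error);
    std::vector<double> d0(n), d1(n);
    std::vector<unsigned char> b0(n), b1(n);
    auto emit = [&](int t, int state) {
        double w = weight[t];
        return (source[t] == state) ? w * lok : w * lerr;
    };
    d0[0] = std::log(0.5) + emit(0, 1);
    d1[0] = std::log(0.5) + emit(0, 2);
    for (int t = 1; t < n; ++t) {
        // state 1
        double stay = d0[t - 1] + lst, sw = d1[t - 1] + lsw;
        if (stay >= sw) { d0[t] = stay; b0[t] = 0; } else { d0[t] = sw; b0[t] = 1; }
        d0[t] += emit(t, 1);
        // state 2
        stay = d1[t - 1] + lst; sw = d0[t - 1] + lsw;
        if (stay >= sw) { d1[t] = stay; b1[t] = 1; } else { d1[t] = sw; b1[t] = 0; }
        d1[t] += emit(t, 2);
    }
    int cur = (d0[n - 1] >= d1[n - 1]) ? 0 : 1;
    path[n - 1] = cur + 1;
    for (int t = n - 1; t > 0; --t) {
        cur = cur == 0 ? b0[t] : b1[t];
        path[t - 1] = cur + 1;
    }
    return path;
}
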