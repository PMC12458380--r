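#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

static inline bool is_acgt(char c) {
    return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// The unit of a period-u run must be primitive (aperiodic), otherwise the run
// is already captured at a smaller unit size (AAAA is a homopolymer, not AAx2).
static bool unit_primitive(const std::string &unit) {
    int u = (int)unit.size();
    for (int d = 1; d < u; ++d) {
        if (u % d != 0) continue;
        bool periodic = true;
        for (int i = d; i < u; ++i)
            if (unit[i] != unit[i - d]) { periodic = false; break; }
        if (periodic) return false;
    }
    return true;
}

// Maximal perfect tandem runs of unit sizes 1..4 in one sequence.
// A run of unit size u is a maximal stretch where seq[i] == seq[i-u]
// (length may include a partial trailing copy).  Runs must have at least
// min_copies[u-1] complete copies and an N-free body.
// Returns 0-based half-open coordinates.
// [[Rcpp::export]]
List cpp_find_runs(std::string seq, IntegerVector unit_sizes, IntegerVector min_copies) {
    int n = (int)seq.size();
    std::vector<int> out_start, out_end, out_ulen;
    std::vector<std::string> out_unit;
    for (R_xlen_t uz = 0; uz < unit_sizes.size(); ++uz) {
        int u = unit_sizes[uz];
        int minc = min_copies[uz];
        int i = u;
        while (i < n) {
            if (!is_acgt(seq[i]) || seq[i] != seq[i - u]) { ++i; continue; }
            int start = i - u; // run includes the u bases before the first match
            bool clean = true;
            for (int j = start; j < i; ++j) if (!is_acgt(seq[j])) { clean = false; break; }
            int j = i;
            while (j < n && is_acgt(seq[j]) && seq[j] == seq[j - u]) ++j;
            int end = j;
            if (clean) {
                int len = end - start;
                if (len / u >= minc) {
                    std::string unit = seq.substr(start, u);
                    if (unit_primitive(unit)) {
                        out_start.push_back(start);
                        out_end.push_back(end);
                        out_unit.push_back(unit);
                        out_ulen.push_back(u);
                    }
                }
            }
            i = end + 1;
        }
    }
    return List::create(_["start"] = wrap(out_start), _["end"] = wrap(out_end),
                        _["unit"] = wrap(out_unit), _["unit_len"] = wrap(out_ulen));
}
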