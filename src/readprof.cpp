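#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>
#include <cstdint>
using namespace Rcpp;

static inline int bcode(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

// Profile a batch of reads aligned to one target sequence.
//
// ref        target sequence (uppercase)
// pos1       1-based leftmost mapping position per read
// cigars     CIGAR strings (M/=/X/I/D/N/S/H/P supported)
// seqs/quals read sequence and ASCII-33 base qualities ("" = absent)
// het_pos    0-based positions of het SNVs on this target (sorted)
// het_other  the alternate haplotype's base at each het position
// het_mask   when true, a mismatch at a het position where the read carries
//            the alternate haplotype's base is not counted as an error
// run_start/run_end  0-based half-open benchmark runs on this target (sorted
//            by start); run observations use `flank` clean flanking bases
//
// Returns aggregate counters; run_spanned/run_correct are parallel to the
// run vectors.
// [[Rcpp::export]]
List cpp_profile_reads(std::string ref, IntegerVector pos1, CharacterVector cigars,
                       CharacterVector seqs, CharacterVector quals,
                       IntegerVector het_pos, CharacterVector het_other, bool het_mask,
                       IntegerVector run_start, IntegerVector run_end, int flank) {
    int nref = (int)ref.size();
    int nreads = pos1.size();
    std::unordered_map<int, char> hets;
    for (R_xlen_t i = 0; i < het_pos.size(); ++i)
        hets[het_pos[i]] = as<std::string>(het_other[i])[0];

    double aligned_bp = 0, clipped_bp = 0, total_read_bp = 0;
    double ins_events = 0, del_events = 0, ins_bp = 0, del_bp = 0;
    NumericMatrix sub_counts(4, 4); // ref base x called base
    const int QMAX = 94;
    NumericMatrix per_q(QMAX, 4);   // aligned, mismatch, ins_events, del_events
    IntegerVector coverage(nref);
    IntegerVector starts(nreads);
    int nruns = run_start.size();
    IntegerVector run_spanned(nruns), run_correct(nruns);

    std::vector<int> q_of_t;       // query index per target offset (-1 = deleted)
    std::vector<unsigned char> mm; // counted-mismatch flag per target offset

    for (int r = 0; r < nreads; ++r) {
        const std::string cig = as<std::string>(cigars[r]);
        const std::string seq = as<std::string>(seqs[r]);
        std::string qual;
        if (!CharacterVector::is_na(quals[r])) qual = as<std::string>(quals[r]);
        bool has_q = qual.size() == seq.size() && qual != "*" && !qual.empty();
        int t0 = pos1[r] - 1;
        starts[r] = t0;
        total_read_bp += (double)seq.size();

        // first pass: target span
        int tspan = 0;
        {
            int len = 0;
            for (char c : cig) {
                if (c >= '0' && c <= '9') { len = len * 10 + (c - '0'); continue; }
                if (c == 'M' || c == '=' || c == 'X' || c == 'D' || c == 'N') tspan += len;
                if (c == 'H') total_read_bp += len; // hard clip not in SEQ
                len = 0;
            }
        }
        q_of_t.assign(tspan, -1);
        mm.assign(tspan, 0);

        int ti = t0, qi = 0, len = 0;
        int last_q = -1; // query index of most recent consumed read base
        for (char c : cig) {
            if (c >= '0' && c <= '9') { len = len * 10 + (c - '0'); continue; }
            switch (c) {
            case 'S':
                clipped_bp += len; qi += len; last_q = qi - 1; break;
            case 'H':
                clipped_bp += len; break;
            case 'M': case '=': case 'X':
                for (int j = 0; j < len; ++j) {
                    int t = ti + j;
                    if (t >= 0 && t < nref) coverage[t]++;
                    int off = t - t0;
                    if (off >= 0 && off < tspan) q_of_t[off] = qi + j;
                    aligned_bp += 1;
                    int qv = -1;
                    if (has_q) {
                        qv = qual[qi + j] - 33;
                        if (qv >= 0 && qv < QMAX) per_q(qv, 0) += 1;
                    }
                    char rb = (t >= 0 && t < nref) ? ref[t] : 'N';
                    char qb = seq[qi + j];
                    int rc = bcode(rb), qc = bcode(qb);
                    if (rc >= 0 && qc >= 0 && rc != qc) {
                        bool masked = false;
                        if (het_mask) {
                            auto it = hets.find(t);
                            if (it != hets.end() && it->second == (char)toupper(qb))
                                masked = true;
                        }
                        if (!masked) {
                            sub_counts(rc, qc) += 1;
                            if (qv >= 0 && qv < QMAX) per_q(qv, 1) += 1;
                            if (off >= 0 && off < tspan) mm[off] = 1;
                        }
                    }
                }
                ti += len; qi += len; last_q = qi - 1; break;
            case 'I':
                ins_events += 1; ins_bp += len;
                if (has_q && last_q >= 0) {
                    int qv = qual[last_q] - 33;
                    if (qv >= 0 && qv < QMAX) per_q(qv, 2) += 1;
                }
                qi += len; last_q = qi - 1; break;
            case 'D':
                del_events += 1; del_bp += len;
                if (has_q && last_q >= 0) {
                    int qv = qual[last_q] - 33;
                    if (qv >= 0 && qv < QMAX) per_q(qv, 3) += 1;
                }
                ti += len; break;
            case 'N':
                ti += len; break;
            case 'P': default:
                break;
            }
            len = 0;
        }

        // run observations: runs fully spanned with both flanks inside [t0, ti)
        if (nruns > 0) {
            int tend = t0 + tspan;
            int lo = 0, hi = nruns;
            while (lo < hi) { int mid = (lo + hi) / 2; if (run_end[mid] + flank <= t0) lo = mid + 1; else hi = mid; }
            for (int k = lo; k < nruns; ++k) {
                int rs = run_start[k], re = run_end[k];
                if (rs - flank >= tend) break;
                if (rs - flank < t0 || re + flank > tend || rs - 1 < t0 || re >= tend)
                    continue;
                run_spanned[k]++;
                int qa = q_of_t[rs - 1 - t0], qb = q_of_t[re - t0];
                bool ok = qa >= 0 && qb >= 0 && (qb - qa - 1) == (re - rs);
                if (ok) {
                    for (int t = rs - flank; t < re + flank && ok; ++t) {
                        int off = t - t0;
                        if (off >= 0 && off < tspan && mm[off]) ok = false;
                    }
                }
                if (ok) run_correct[k]++;
            }
        }
    }

    return List::create(
        _["aligned_bp"] = aligned_bp, _["clipped_bp"] = clipped_bp,
        _["total_read_bp"] = total_read_bp,
        _["sub_counts"] = sub_counts,
        _["ins_events"] = ins_events, _["del_events"] = del_events,
        _["ins_bp"] = ins_bp, _["del_bp"] = del_bp,
        _["per_q"] = per_q, _["coverage"] = coverage, _["starts"] = starts,
        _["run_spanned"] = run_spanned, _["run_correct"] = run_correct);
}
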