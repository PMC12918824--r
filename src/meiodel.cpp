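#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap alignment, global in the read, local in the reference (free end
// gaps on the reference). Returns the best-scoring path with a deterministic
// tie rule (diagonal > read-gap > ref-gap; smallest end column), per-operation
// read/reference offsets, and the vector of best scores per reference end
// column (used for the mapping-confidence margin).
//
// Gap of length L costs gap_open + L * gap_ext (both supplied negative).
// [[Rcpp::export]]
List cpp_align_glocal(std::string read, std::string ref,
                      double match = 1.0, double mismatch = -4.0,
                      double gap_open = -6.0, double gap_ext = -1.0) {
    const int m = (int) read.size(), n = (int) ref.size();
    if (m == 0 || n == 0) stop("empty sequence");
    const double NEG = -1e18;
    // score matrices, (m+1) x (n+1), row-major
    std::vector<double> M((size_t)(m + 1) * (n + 1), NEG);
    std::vector<double> X = M; // gap in reference (insertion in read)
    std::vector<double> Y = M; // gap in read (deletion of reference)
    std::vector<unsigned char> tbM((size_t)(m + 1) * (n + 1), 0);
    std::vector<unsigned char> tbX = tbM, tbY = tbM;
    auto at = [n](int i, int j) { return (size_t) i * (n + 1) + j; };

    for (int j = 0; j <= n; ++j) M[at(0, j)] = 0.0; // free reference prefix
    for (int i = 1; i <= m; ++i) {                  // leading read insertion
        X[at(i, 0)] = gap_open + gap_ext * i;
        tbX[at(i, 0)] = 1;
    }
    for (int i = 1; i <= m; ++i) {
        const char rc = read[i - 1];
        for (int j = 1; j <= n; ++j) {
            const double sub = (rc == ref[j - 1]) ? match : mismatch;
            // M: ties prefer M > X > Y
            double best = M[at(i - 1, j - 1)]; unsigned char tb = 0;
            if (X[at(i - 1, j - 1)] > best) { best = X[at(i - 1, j - 1)]; tb = 1; }
            if (Y[at(i - 1, j - 1)] > best) { best = Y[at(i - 1, j - 1)]; tb = 2; }
            M[at(i, j)] = best + sub; tbM[at(i, j)] = tb;
            // X consumes read base i
            double xo = M[at(i - 1, j)] + gap_open + gap_ext;
            double xe = X[at(i - 1, j)] + gap_ext;
            if (xo >= xe) { X[at(i, j)] = xo; tbX[at(i, j)] = 0; }
            else          { X[at(i, j)] = xe; tbX[at(i, j)] = 1; }
            // Y consumes reference base j
            double yo = M[at(i, j - 1)] + gap_open + gap_ext;
            double ye = Y[at(i, j - 1)] + gap_ext;
            if (yo >= ye) { Y[at(i, j)] = yo; tbY[at(i, j)] = 0; }
            else          { Y[at(i, j)] = ye; tbY[at(i, j)] = 1; }
        }
    }
    // alignment must end by consuming the last read base (state M or X)
    NumericVector row(n + 1);
    int jbest = 0; double sbest = NEG;
    for (int j = 0; j <= n; ++j) {
        double s = std::max(M[at(m, j)], X[at(m, j)]);
        row[j] = s;
        if (s > sbest) { sbest = s; jbest = j; }
    }
    // traceback
    int i = m, j = jbest;
    int state = (M[at(m, jbest)] >= X[at(m, jbest)]) ? 0 : 1;
    std::vector<char> ops; std::vector<int> lens, rdpos, rfpos;
    int nmatch = 0, nmismatch = 0;
    auto push = [&](char op, int rd, int rf) {
        if (!ops.empty() && ops.back() == op) { lens.back()++; rdpos.back() = rd; rfpos.back() = rf; }
        else { ops.push_back(op); lens.push_back(1); rdpos.push_back(rd); rfpos.push_back(rf); }
    };
    while (i > 0) {
        if (state == 0) {
            unsigned char tb = tbM[at(i, j)];
            if (read[i - 1] == ref[j - 1]) nmatch++; else nmismatch++;
            push('M', i - 1, j - 1);
            i--; j--; state = tb;
        } else if (state == 1) {
            unsigned char tb = tbX[at(i, j)];
            push('I', i - 1, j); // insertion sits before ref position j (0-based)
            i--; state = (tb == 0) ? 0 : 1;
        } else {
            unsigned char tb = tbY[at(i, j)];
            push('D', i, j - 1);
            j--; state = (tb == 0) ? 0 : 2;
        }
    }
    const int ref_start = j; // 0-based; alignment covers ref [ref_start, jbest)
    // ops were collected in reverse
    std::reverse(ops.begin(), ops.end());
    std::reverse(lens.begin(), lens.end());
    std::reverse(rdpos.begin(), rdpos.end());
    std::reverse(rfpos.begin(), rfpos.end());
    // per-op start offsets (0-based): rdpos/rfpos currently hold the *first*
    // consumed position after reversal bookkeeping; recompute cleanly
    int k = (int) ops.size();
    IntegerVector op_len(k), op_read0(k), op_ref0(k);
    CharacterVector op_chr(k);
    int rd = 0, rf = ref_start;
    for (int t = 0; t < k; ++t) {
        op_chr[t] = std::string(1, ops[t]);
        op_len[t] = lens[t];
        op_read0[t] = rd; op_ref0[t] = rf;
        if (ops[t] == 'M') { rd += lens[t]; rf += lens[t]; }
        else if (ops[t] == 'I') { rd += lens[t]; }
        else { rf += lens[t]; }
    }
    return List::create(
        _["score"] = sbest, _["ref_start"] = ref_start, _["ref_end"] = jbest,
        _["op"] = op_chr, _["len"] = op_len,
        _["read0"] = op_read0, _["ref0"] = op_ref0,
        _["nmatch"] = nmatch, _["nmismatch"] = nmismatch,
        _["end_scores"] = row);
}

// Best ungapped overlap between the 3' end of read 1 and the 5' end of the
// reverse-complemented read 2 (FLASH-style). Candidate overlap o aligns the
// last o bases of s1 with the first o bases of s2rc; valid overlaps have
// o >= min_overlap and mismatches <= max_mm_frac * o. Best = most
// (matches - mismatches); ties broken toward the longer overlap.
// [[Rcpp::export]]
List cpp_best_overlap(std::string s1, std::string s2rc,
                      int min_overlap = 20, double max_mm_frac = 0.10) {
    const int n1 = (int) s1.size(), n2 = (int) s2rc.size();
    const int omax = std::min(n1, n2);
    int best_o = 0, best_mm = 0; double best_score = -1e18;
    for (int o = min_overlap; o <= omax; ++o) {
        int mm = 0;
        const char *a = s1.data() + (n1 - o), *b = s2rc.data();
        for (int t = 0; t < o; ++t) if (a[t] != b[t]) mm++;
        if (mm > max_mm_frac * o) continue;
        double sc = (o - mm) - mm;
        if (sc > best_score || (sc == best_score && o > best_o)) {
            best_score = sc; best_o = o; best_mm = mm;
        }
    }
    return List::create(_["overlap"] = best_o, _["mismatches"] = best_mm);
}
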