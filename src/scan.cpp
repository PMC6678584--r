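// Exhaustive substitution-only scanning of short queries against longer
// subject sequences.  Two entry points:
//
//  * scan_matches_cpp: end-to-end hits with at most max_mm mismatches,
//    optionally on both strands (replaces the role of an external short-read
//    aligner for desk-scale genomes and blocklists).
//
//  * align_tail_cpp: plus-strand end-to-end hits allowing a maximal
//    non-templated 3' suffix (<= max_tail nt, including any overhang past
//    the subject 3' end) split off as a soft tail, with at most
//    max_internal_mm substitutions in the remaining templated portion.
//
// Mismatches are reported 1-based on the subject as "pos:REF>ALT"
// (comma-separated); minus-strand hits are reported in plus-strand subject
// coordinates with the query reverse-complemented before comparison.

#include <Rcpp.h>
#include <string>
#include <vector>
#include <sstream>
using namespace Rcpp;

static char comp(char c) {
    switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'U': return 'A';
    default:  return 'N';
    }
}

static std::string revcomp(const std::string& s) {
    std::string r(s.rbegin(), s.rend());
    for (size_t i = 0; i < r.size(); ++i) r[i] = comp(r[i]);
    return r;
}

// [[Rcpp::export]]
DataFrame scan_matches_cpp(CharacterVector queries, CharacterVector subjects,
                           int max_mm, bool both_strands) {
    std::vector<int> o_query, o_subject, o_start, o_nmm;
    std::vector<std::string> o_strand, o_mm;

    for (int qi = 0; qi < queries.size(); ++qi) {
        const std::string fwd = as<std::string>(queries[qi]);
        const int n = fwd.size();
        if (n == 0) continue;
        const std::string rev = both_strands ? revcomp(fwd) : std::string();
        for (int si = 0; si < subjects.size(); ++si) {
            const std::string sub = as<std::string>(subjects[si]);
            const int L = sub.size();
            for (int strand = 0; strand < (both_strands ? 2 : 1); ++strand) {
                const std::string& q = (strand == 0) ? fwd : rev;
                for (int s = 0; s + n <= L; ++s) {
                    int nm = 0;
                    for (int p = 0; p < n; ++p) {
                        if (sub[s + p] != q[p] && ++nm > max_mm) break;
                    }
                    if (nm > max_mm) continue;
                    std::ostringstream mm;
                    if (nm > 0) {
                        bool first = true;
                        for (int p = 0; p < n; ++p) {
                            if (sub[s + p] == q[p]) continue;
                            if (!first) mm << ",";
                            mm << (s + p + 1) << ":" << sub[s + p] << ">" << q[p];
                            first = false;
                        }
                    }
                    o_query.push_back(qi + 1);
                    o_subject.push_back(si + 1);
                    o_strand.push_back(strand == 0 ? "+" : "-");
                    o_start.push_back(s + 1);
                    o_nmm.push_back(nm);
                    o_mm.push_back(mm.str());
                }
            }
        }
    }
    return DataFrame::create(
        _["query"] = o_query, _["subject"] = o_subject, _["strand"] = o_strand,
        _["start"] = o_start, _["nmm"] = o_nmm, _["mm"] = o_mm,
        _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
DataFrame align_tail_cpp(CharacterVector queries, CharacterVector subjects,
                         int max_internal_mm, int max_tail) {
    std::vector<int> o_query, o_subject, o_start, o_tpl_len, o_nmm;
    std::vector<std::string> o_mm, o_tail;

    std::vector<std::string> subs(subjects.size());
    for (int si = 0; si < subjects.size(); ++si)
        subs[si] = as<std::string>(subjects[si]);

    for (int qi = 0; qi < queries.size(); ++qi) {
        const std::string q = as<std::string>(queries[qi]);
        const int n = q.size();
        if (n <= max_tail) continue;
        for (int si = 0; si < (int)subs.size(); ++si) {
            const std::string& sub = subs[si];
            const int L = sub.size();
            // allow up to max_tail nt of the query to overhang the subject 3' end
            for (int s = 0; s + (n - max_tail) <= L; ++s) {
                const int overhang = std::max(0, s + n - L);
                if (overhang > max_tail) break;
                const int cov = n - overhang;  // bases lying on the subject
                // any salvageable alignment has at most
                // max_internal_mm + (max_tail - overhang) mismatches
                const int cap = max_internal_mm + max_tail - overhang;
                int nm_quick = 0;
                for (int p = 0; p < cov; ++p)
                    if (sub[s + p] != q[p] && ++nm_quick > cap) break;
                if (nm_quick > cap) continue;
                std::vector<int> mmpos;
                for (int p = 0; p < cov; ++p)
                    if (sub[s + p] != q[p]) mmpos.push_back(p);
                // trailing run of contiguous mismatches ending at the last
                // templated base becomes (part of) the soft tail
                int run = 0;
                while (run < (int)mmpos.size() &&
                       mmpos[mmpos.size() - 1 - run] == cov - 1 - run) ++run;
                const int tail_from_template = std::min(run, max_tail - overhang);
                const int tail_len = overhang + tail_from_template;
                const int tpl_len = n - tail_len;
                if (tpl_len < 1) continue;
                const int internal = (int)mmpos.size() - tail_from_template;
                if (internal > max_internal_mm) continue;
                std::ostringstream mm;
                bool first = true;
                for (size_t t = 0; t < mmpos.size(); ++t) {
                    if (mmpos[t] >= tpl_len) break;
                    if (!first) mm << ",";
                    mm << (s + mmpos[t] + 1) << ":" << sub[s + mmpos[t]] << ">"
                       << q[mmpos[t]];
                    first = false;
                }
                o_query.push_back(qi + 1);
                o_subject.push_back(si + 1);
                o_start.push_back(s + 1);
                o_tpl_len.push_back(tpl_len);
                o_nmm.push_back(internal);
                o_mm.push_back(mm.str());
                o_tail.push_back(q.substr(tpl_len));
            }
        }
    }
    return DataFrame::create(
        _["query"] = o_query, _["subject"] = o_subject, _["start"] = o_start,
        _["tpl_len"] = o_tpl_len, _["nmm"] = o_nmm, _["mm"] = o_mm,
        _["tail"] = o_tail, _["stringsAsFactors"] = false);
}
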