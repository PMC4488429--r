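#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <string>

using namespace Rcpp;

// Byte-level sequence kernels shared by the baiting and assembly stages.
// Alphabet is {A,C,G,T,N}; any k-mer containing a non-ACGT byte is skipped.
// "Canonical" k-mer = lexicographic (byte) min of the k-mer and its reverse
// complement, well-defined for odd k (no self-complementary k-mers).

static inline char comp_base(char c) {
    switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    case 'N': return 'N';
    default:  return 0; // invalid
    }
}

static bool revcomp_str(const std::string& s, std::string& out) {
    size_t n = s.size();
    out.resize(n);
    for (size_t i = 0; i < n; ++i) {
        char c = comp_base(s[n - 1 - i]);
        if (c == 0) return false;
        out[i] = c;
    }
    return true;
}

// [[Rcpp::export]]
CharacterVector C_revcomp(CharacterVector seqs) {
    R_xlen_t n = seqs.size();
    CharacterVector out(n);
    std::string rc;
    for (R_xlen_t i = 0; i < n; ++i) {
        if (seqs[i] == NA_STRING) { out[i] = NA_STRING; continue; }
        std::string s = as<std::string>(seqs[i]);
        if (!revcomp_str(s, rc))
            stop("invalid character in sequence %d (alphabet is A,C,G,T,N)", (int)(i + 1));
        out[i] = rc;
    }
    if (seqs.hasAttribute("names")) out.names() = seqs.names();
    return out;
}

// Minimum Phred score per quality string (ASCII - 33); NA for empty strings.
// [[Rcpp::export]]
IntegerVector C_min_phred(CharacterVector quals) {
    R_xlen_t n = quals.size();
    IntegerVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        if (quals[i] == NA_STRING) { out[i] = NA_INTEGER; continue; }
        const char* q = CHAR(quals[i]);
        size_t len = strlen(q);
        if (len == 0) { out[i] = NA_INTEGER; continue; }
        int mn = 255;
        for (size_t j = 0; j < len; ++j) {
            int v = (unsigned char)q[j] - 33;
            if (v < mn) mn = v;
        }
        out[i] = mn;
    }
    return out;
}

static inline bool kmer_valid(const char* s, size_t pos, int k) {
    for (int j = 0; j < k; ++j) {
        char c = s[pos + j];
        if (c != 'A' && c != 'C' && c != 'G' && c != 'T') return false;
    }
    return true;
}

// canonical form of s[pos, pos+k) written into buf (which must hold k chars);
// returns pointer to the canonical representation
static const char* canon_kmer(const char* s, size_t pos, int k, std::string& buf) {
    buf.resize(k);
    for (int j = 0; j < k; ++j) buf[j] = comp_base(s[pos + k - 1 - j]);
    // byte compare forward k-mer vs rc in buf
    int cmp = strncmp(s + pos, buf.data(), k);
    if (cmp <= 0) return s + pos; // forward is canonical (ties impossible for odd k)
    return buf.data();
}

// Canonical k-mer spectrum of a set of sequences.  When circular = TRUE each
// sequence is treated as a circle (wrap-around k-mers included).
// [[Rcpp::export]]
List C_kmer_spectrum(CharacterVector seqs, int k, bool circular) {
    if (k < 1) stop("k must be positive");
    std::unordered_map<std::string, int> counts;
    std::string rcbuf, ext;
    for (R_xlen_t i = 0; i < seqs.size(); ++i) {
        if (seqs[i] == NA_STRING) continue;
        std::string s = as<std::string>(seqs[i]);
        if (circular && (int)s.size() >= k) {
            ext = s + s.substr(0, k - 1);
            s = ext;
        }
        if ((int)s.size() < k) continue;
        size_t last = s.size() - k;
        const char* cs = s.c_str();
        for (size_t pos = 0; pos <= last; ++pos) {
            if (!kmer_valid(cs, pos, k)) continue;
            const char* cp = canon_kmer(cs, pos, k, rcbuf);
            counts[std::string(cp, k)] += 1;
        }
    }
    size_t m = counts.size();
    CharacterVector kmers(m);
    IntegerVector cnt(m);
    size_t idx = 0;
    for (auto& kv : counts) {
        kmers[idx] = kv.first;
        cnt[idx] = kv.second;
        ++idx;
    }
    return List::create(_["kmer"] = kmers, _["count"] = cnt);
}

// Canonical (byte-min of string and its reverse complement) form of each
// input string.  Used for orientation-free comparison of k-mers and contigs.
// [[Rcpp::export]]
CharacterVector C_canonical(CharacterVector seqs) {
    R_xlen_t n = seqs.size();
    CharacterVector out(n);
    std::string rc;
    for (R_xlen_t i = 0; i < n; ++i) {
        if (seqs[i] == NA_STRING) { out[i] = NA_STRING; continue; }
        std::string s = as<std::string>(seqs[i]);
        if (!revcomp_str(s, rc))
            stop("invalid character in sequence %d", (int)(i + 1));
        out[i] = (s.compare(rc) <= 0) ? s : rc;
    }
    return out;
}

// Per-sequence count of positions whose canonical k-mer belongs to `seeds`
// (seeds assumed already canonical, all of length k).
// [[Rcpp::export]]
IntegerVector C_seed_hits(CharacterVector seqs, CharacterVector seeds, int k) {
    std::unordered_set<std::string> seedset;
    for (R_xlen_t i = 0; i < seeds.size(); ++i)
        seedset.insert(as<std::string>(seeds[i]));
    R_xlen_t n = seqs.size();
    IntegerVector out(n);
    std::string rcbuf;
    for (R_xlen_t i = 0; i < n; ++i) {
        if (seqs[i] == NA_STRING) { out[i] = 0; continue; }
        const char* cs = CHAR(seqs[i]);
        size_t len = strlen(cs);
        int hits = 0;
        if ((int)len >= k) {
            size_t last = len - k;
            for (size_t pos = 0; pos <= last; ++pos) {
                if (!kmer_valid(cs, pos, k)) continue;
                const char* cp = canon_kmer(cs, pos, k, rcbuf);
                if (seedset.count(std::string(cp, k))) ++hits;
            }
        }
        out[i] = hits;
    }
    return out;
}
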