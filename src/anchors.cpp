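#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// Unique-anchor machinery for whole-haplotype comparison and gene placement.
// Anchors are exact matches seeded at k-mers occurring exactly once in the
// relevant sequence(s), extended maximally, merged along diagonals, then
// chained by a weighted longest-increasing-subsequence DP.

static inline int base2bit(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

struct KIndex {
  // kmer -> position; multi-occurrence marked with pos = -1
  std::unordered_map<uint64_t, int64_t> map;
};

static void index_kmers(const std::string& s, int k, KIndex& idx) {
  const int64_t n = (int64_t)s.size();
  if (n < k) return;
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t h = 0; int run = 0;
  for (int64_t i = 0; i < n; ++i) {
    int b = base2bit(s[i]);
    if (b < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)b) & mask;
    if (++run >= k) {
      int64_t pos = i - k + 1;
      auto it = idx.map.find(h);
      if (it == idx.map.end()) idx.map.emplace(h, pos);
      else it->second = -1;
    }
  }
}

struct Anchor { int64_t rs, qs, len; };

// [[Rcpp::export(name = ".find_anchors")]]
DataFrame find_anchors(std::string ref, std::string qry, int min_anchor) {
  if (min_anchor < 8 || min_anchor > 32)
    stop("min_anchor must be in [8, 32]");
  const int k = min_anchor;
  KIndex ridx, qidx;
  index_kmers(ref, k, ridx);
  index_kmers(qry, k, qidx);

  // seeds: k-mers unique in both
  std::vector<Anchor> seeds;
  {
    const int64_t n = (int64_t)qry.size();
    uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    uint64_t h = 0; int run = 0;
    for (int64_t i = 0; i < n; ++i) {
      int b = base2bit(qry[i]);
      if (b < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)b) & mask;
      if (++run >= k) {
        int64_t qpos = i - k + 1;
        auto qi = qidx.map.find(h);
        if (qi == qidx.map.end() || qi->second < 0) continue; // multi in qry
        auto ri = ridx.map.find(h);
        if (ri == ridx.map.end() || ri->second < 0) continue; // absent/multi
        seeds.push_back({ri->second, qpos, (int64_t)k});
      }
    }
  }
  if (seeds.empty())
    return DataFrame::create(_["ref_start"] = IntegerVector(0),
                             _["ref_end"] = IntegerVector(0),
                             _["qry_start"] = IntegerVector(0),
                             _["qry_end"] = IntegerVector(0));

  // merge seeds on the same diagonal into runs
  std::sort(seeds.begin(), seeds.end(), [](const Anchor& a, const Anchor& b) {
    int64_t da = a.rs - a.qs, db = b.rs - b.qs;
    if (da != db) return da < db;
    return a.rs < b.rs;
  });
  std::vector<Anchor> merged;
  for (const auto& s : seeds) {
    if (!merged.empty()) {
      Anchor& last = merged.back();
      if (last.rs - last.qs == s.rs - s.qs && s.rs <= last.rs + last.len) {
        int64_t newend = s.rs + s.len;
        if (newend > last.rs + last.len) last.len = newend - last.rs;
        continue;
      }
    }
    merged.push_back(s);
  }
  // maximal extension of each run
  const int64_t rn = (int64_t)ref.size(), qn = (int64_t)qry.size();
  for (auto& a : merged) {
    while (a.rs > 0 && a.qs > 0 && ref[a.rs - 1] == qry[a.qs - 1]) {
      --a.rs; --a.qs; ++a.len;
    }
    while (a.rs + a.len < rn && a.qs + a.len < qn &&
           ref[a.rs + a.len] == qry[a.qs + a.len]) ++a.len;
  }
  // dedupe anchors that extended to the same maximal match
  std::sort(merged.begin(), merged.end(), [](const Anchor& a, const Anchor& b) {
    if (a.rs != b.rs) return a.rs < b.rs;
    if (a.qs != b.qs) return a.qs < b.qs;
    return a.len > b.len;
  });
  merged.erase(std::unique(merged.begin(), merged.end(),
      [](const Anchor& a, const Anchor& b) {
        return a.rs == b.rs && a.qs == b.qs;
      }), merged.end());

  // weighted LIS chain: maximize total anchor length, both start coordinates
  // strictly increasing (overlaps allowed -- they carry the tandem signal)
  const size_t n = merged.size();
  std::vector<double> best(n);
  std::vector<int64_t> prev(n, -1);
  double glob = -1.0; int64_t gi = -1;
  for (size_t i = 0; i < n; ++i) {
    best[i] = (double)merged[i].len;
    for (size_t j = 0; j < i; ++j) {
      if (merged[j].rs < merged[i].rs && merged[j].qs < merged[i].qs &&
          merged[j].rs + merged[j].len <= merged[i].rs + merged[i].len &&
          merged[j].qs + merged[j].len <= merged[i].qs + merged[i].len) {
        double cand = best[j] + (double)merged[i].len;
        if (cand > best[i]) { best[i] = cand; prev[i] = (int64_t)j; }
      }
    }
    if (best[i] > glob) { glob = best[i]; gi = (int64_t)i; }
  }
  std::vector<size_t> chain;
  for (int64_t i = gi; i >= 0; i = prev[i]) chain.push_back((size_t)i);
  std::reverse(chain.begin(), chain.end());

  const size_t cn = chain.size();
  IntegerVector rs(cn), re(cn), qs(cn), qe(cn);
  for (size_t i = 0; i < cn; ++i) {
    const Anchor& a = merged[chain[i]];
    rs[i] = (int)a.rs; re[i] = (int)(a.rs + a.len);
    qs[i] = (int)a.qs; qe[i] = (int)(a.qs + a.len);
  }
  return DataFrame::create(_["ref_start"] = rs, _["ref_end"] = re,
                           _["qry_start"] = qs, _["qry_end"] = qe);
}

// Seed-and-chain placement of CDS sequences on a reference sequence set.
// Reference k-mers indexed once (unique-in-reference); each CDS walked in
// both orientations, seeds chained per chromosome by an LIS on reference
// position; best chain's hull reported with seed-coverage identity.

// [[Rcpp::export(name = ".place_cds")]]
DataFrame place_cds(CharacterVector ref_seqs, CharacterVector cds_seqs,
                    int k) {
  if (k < 8 || k > 32) stop("k must be in [8, 32]");
  struct RefHit { int32_t chrom; int64_t pos; };
  std::unordered_map<uint64_t, RefHit> idx; // pos = -1 marks multi
  for (int c = 0; c < ref_seqs.size(); ++c) {
    std::string s = as<std::string>(ref_seqs[c]);
    const int64_t n = (int64_t)s.size();
    if (n < k) continue;
    uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    uint64_t h = 0; int run = 0;
    for (int64_t i = 0; i < n; ++i) {
      int b = base2bit(s[i]);
      if (b < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)b) & mask;
      if (++run >= k) {
        auto it = idx.find(h);
        if (it == idx.end()) idx.emplace(h, RefHit{(int32_t)c, i - k + 1});
        else it->second.pos = -1;
      }
    }
  }

  const int ng = cds_seqs.size();
  IntegerVector chrom(ng), start(ng), end(ng), nseed(ng);
  NumericVector ident(ng);
  CharacterVector strand(ng);
  struct Seed { int64_t cpos, rpos; };

  for (int g = 0; g < ng; ++g) {
    std::string cds = as<std::string>(cds_seqs[g]);
    double bestcov = 0.0; int bchrom = -1; int64_t bs = 0, be = 0;
    int bnseed = 0; char bstrand = '+';
    for (int ori = 0; ori < 2; ++ori) {
      std::string s;
      if (ori == 0) s = cds;
      else {
        s.resize(cds.size());
        for (size_t i = 0; i < cds.size(); ++i) {
          char c = cds[cds.size() - 1 - i];
          s[i] = (c == 'A') ? 'T' : (c == 'T') ? 'A'
               : (c == 'C') ? 'G' : (c == 'G') ? 'C' : c;
        }
      }
      const int64_t n = (int64_t)s.size();
      if (n < k) continue;
      // collect unique-in-reference seed hits, grouped by chromosome
      std::unordered_map<int32_t, std::vector<Seed>> bychrom;
      uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
      uint64_t h = 0; int run = 0;
      for (int64_t i = 0; i < n; ++i) {
        int b = base2bit(s[i]);
        if (b < 0) { run = 0; h = 0; continue; }
        h = ((h << 2) | (uint64_t)b) & mask;
        if (++run >= k) {
          auto it = idx.find(h);
          if (it != idx.end() && it->second.pos >= 0)
            bychrom[it->second.chrom].push_back({i - k + 1, it->second.pos});
        }
      }
      for (auto& kv : bychrom) {
        std::vector<Seed>& sd = kv.second;
        std::sort(sd.begin(), sd.end(), [](const Seed& a, const Seed& b) {
          if (a.cpos != b.cpos) return a.cpos < b.cpos;
          return a.rpos < b.rpos;
        });
        // LIS on rpos (strictly increasing), chain weight = seed count
        const size_t m = sd.size();
        std::vector<int> dp(m, 1); std::vector<int64_t> pr(m, -1);
        int bi = 0;
        for (size_t i = 0; i < m; ++i) {
          for (size_t j = 0; j < i; ++j) {
            if (sd[j].rpos < sd[i].rpos && sd[j].cpos < sd[i].cpos &&
                dp[j] + 1 > dp[i]) {
              dp[i] = dp[j] + 1; pr[i] = (int64_t)j;
            }
          }
          if (dp[i] > dp[bi]) bi = (int)i;
        }
        // coverage of CDS by chained seeds (union of seed intervals)
        std::vector<std::pair<int64_t, int64_t>> ivs;
        for (int64_t i = bi; i >= 0; i = pr[i])
          ivs.push_back({sd[i].cpos, sd[i].cpos + k});
        std::reverse(ivs.begin(), ivs.end());
        int64_t cov = 0, cs = -1, ce = -1;
        for (auto& iv : ivs) {
          if (cs < 0) { cs = iv.first; ce = iv.second; continue; }
          if (iv.first > ce) { cov += ce - cs; cs = iv.first; ce = iv.second; }
          else if (iv.second > ce) ce = iv.second;
        }
        if (cs >= 0) cov += ce - cs;
        double covfrac = (double)cov / (double)n;
        if (covfrac > bestcov) {
          bestcov = covfrac; bchrom = kv.first;
          // hull on reference
          int64_t rmin = INT64_MAX, rmax = INT64_MIN;
          for (int64_t i = bi; i >= 0; i = pr[i]) {
            if (sd[i].rpos < rmin) rmin = sd[i].rpos;
            if (sd[i].rpos + k > rmax) rmax = sd[i].rpos + k;
          }
          bs = rmin; be = rmax; bnseed = dp[bi];
          bstrand = (ori == 0) ? '+' : '-';
        }
      }
    }
    if (bchrom < 0) {
      chrom[g] = NA_INTEGER; start[g] = NA_INTEGER; end[g] = NA_INTEGER;
      ident[g] = NA_REAL; nseed[g] = 0; strand[g] = NA_STRING;
    } else {
      chrom[g] = bchrom + 1; start[g] = (int)bs; end[g] = (int)be;
      ident[g] = bestcov; nseed[g] = bnseed;
      strand[g] = (bstrand == '+') ? "+" : "-";
    }
  }
  return DataFrame::create(_["chrom_idx"] = chrom, _["ref_start"] = start,
                           _["ref_end"] = end, _["identity"] = ident,
                           _["n_seeds"] = nseed, _["strand"] = strand);
}
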