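// Extended-connectivity environment enumeration.
//
// Identifiers are 32-bit FNV-1a hashes of human-readable key strings:
//   radius 0:  "A <atomic_num> <degree> <n_h> <charge> <in_ring>"
//   radius r:  "E <r> <center_id> <pair,pair,...>"  with pairs
//              "<order>:<neighbor_id>" sorted lexicographically, order
//              printed as "1", "1.5", "2" or "3".
// The R-level .hash_string() implements the same FNV-1a and is used in
// tests to pin these identifiers independently of this file.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

static uint32_t fnv1a(const std::string& s) {
  uint32_t h = 2166136261u;
  for (unsigned char c : s) {
    h ^= c;
    h *= 16777619u;
  }
  return h;
}

static std::string order_str(double o) {
  if (o == 1.5) return "1.5";
  char buf[8];
  snprintf(buf, sizeof(buf), "%d", (int)o);
  return std::string(buf);
}

// [[Rcpp::export(name = ".ecfp_envs_cpp")]]
List ecfp_envs_cpp(IntegerVector atomic_num, IntegerVector degree,
                   IntegerVector n_h, IntegerVector charge,
                   IntegerVector in_ring, IntegerVector bond_from,
                   IntegerVector bond_to, NumericVector bond_order,
                   int radius) {
  const int n = atomic_num.size();
  const int nb = bond_from.size();

  std::vector<std::vector<int>> adj(n);
  std::vector<std::vector<double>> adj_ord(n);
  for (int k = 0; k < nb; ++k) {
    int a = bond_from[k] - 1, b = bond_to[k] - 1;
    adj[a].push_back(b); adj_ord[a].push_back(bond_order[k]);
    adj[b].push_back(a); adj_ord[b].push_back(bond_order[k]);
  }

  std::vector<int> out_center, out_radius;
  std::vector<double> out_id;
  std::vector<std::string> out_key;

  std::vector<uint32_t> ids(n);
  std::vector<std::vector<int>> cover(n);
  char buf[96];
  for (int a = 0; a < n; ++a) {
    snprintf(buf, sizeof(buf), "A %d %d %d %d %d", atomic_num[a], degree[a],
             n_h[a], charge[a], in_ring[a]);
    ids[a] = fnv1a(buf);
    cover[a] = {a};
    out_center.push_back(a + 1);
    out_radius.push_back(0);
    out_id.push_back((double)ids[a]);
    out_key.push_back(std::to_string(a));
  }

  for (int r = 1; r <= radius; ++r) {
    std::vector<uint32_t> nids(n);
    std::vector<std::vector<int>> ncover(n);
    for (int a = 0; a < n; ++a) {
      if (adj[a].empty()) {
        nids[a] = ids[a];
        ncover[a] = cover[a];
      } else {
        std::vector<std::string> pairs;
        pairs.reserve(adj[a].size());
        for (size_t j = 0; j < adj[a].size(); ++j) {
          pairs.push_back(order_str(adj_ord[a][j]) + ":" +
                          std::to_string(ids[adj[a][j]]));
        }
        std::sort(pairs.begin(), pairs.end());
        std::string key = "E " + std::to_string(r) + " " +
                          std::to_string(ids[a]) + " ";
        for (size_t j = 0; j < pairs.size(); ++j) {
          if (j) key += ",";
          key += pairs[j];
        }
        nids[a] = fnv1a(key);
        std::vector<int> cov = cover[a];
        for (int b : adj[a])
          cov.insert(cov.end(), cover[b].begin(), cover[b].end());
        std::sort(cov.begin(), cov.end());
        cov.erase(std::unique(cov.begin(), cov.end()), cov.end());
        ncover[a] = cov;
      }
      std::string k;
      for (size_t j = 0; j < ncover[a].size(); ++j) {
        if (j) k += ",";
        k += std::to_string(ncover[a][j]);
      }
      out_center.push_back(a + 1);
      out_radius.push_back(r);
      out_id.push_back((double)nids[a]);
      out_key.push_back(k);
    }
    ids.swap(nids);
    cover.swap(ncover);
  }

  return List::create(_["center"] = wrap(out_center),
                      _["radius"] = wrap(out_radius),
                      _["id"] = wrap(out_id),
                      _["atom_key"] = wrap(out_key));
}
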