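#include <Rcpp.h>
#include <cstdint>
#include <cstdio>
using namespace Rcpp;

// FNV-1a 64-bit hash, used for salted user-id anonymization and for the run
// manifest checksums. Deterministic for a fixed salt, not reversible.
// [[Rcpp::export(name = ".fnv1a64")]]
CharacterVector fnv1a64(CharacterVector x, std::string salt) {
  const uint64_t prime = 1099511628211ULL;
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    if (CharacterVector::is_na(x[i])) {
      out[i] = NA_STRING;
      continue;
    }
    std::string s = salt + std::string(x[i]);
    uint64_t h = 14695981039346656037ULL;
    for (unsigned char c : s) {
      h ^= c;
      h *= prime;
    }
    char buf[17];
    std::snprintf(buf, sizeof(buf), "%016llx", static_cast<unsigned long long>(h));
    out[i] = buf;
  }
  return out;
}
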