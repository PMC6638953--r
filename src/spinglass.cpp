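#include <Rcpp.h>
using namespace Rcpp;

// Simulated annealing for the signed Reichardt-Bornholdt Hamiltonian
// H(sigma) = -sum_{i<j} A_ij * delta(sigma_i, sigma_j), with A the signed
// coupling matrix (observed minus gamma times the configuration null,
// positive layer minus negative layer). Uses R's RNG so runs are
// reproducible under set.seed().
//
// [[Rcpp::export]]
List anneal_spinglass_cpp(NumericMatrix A, int spins, double start_temp,
                          double stop_temp, double cooling_factor,
                          int sweeps_per_temp) {
  const int k = A.nrow();
  IntegerVector sigma(k);
  for (int i = 0; i < k; ++i) sigma[i] = (int)(unif_rand() * spins);
  std::vector<int> order(k);
  for (int i = 0; i < k; ++i) order[i] = i;

  for (double temp = start_temp; temp >= stop_temp; temp *= cooling_factor) {
    for (int s = 0; s < sweeps_per_temp; ++s) {
      // Fisher-Yates shuffle for the node visit order
      for (int i = k - 1; i > 0; --i) {
        int j = (int)(unif_rand() * (i + 1));
        std::swap(order[i], order[j]);
      }
      for (int t = 0; t < k; ++t) {
        const int i = order[t];
        int prop = (int)(unif_rand() * spins);
        if (prop == sigma[i]) continue;
        double sum_new = 0.0, sum_old = 0.0;
        for (int j = 0; j < k; ++j) {
          if (j == i) continue;
          if (sigma[j] == prop) sum_new += A(i, j);
          else if (sigma[j] == sigma[i]) sum_old += A(i, j);
        }
        const double dH = -(sum_new - sum_old);
        if (dH <= 0.0 || unif_rand() < std::exp(-dH / temp)) sigma[i] = prop;
      }
    }
  }
  double H = 0.0;
  for (int i = 0; i < k - 1; ++i)
    for (int j = i + 1; j < k; ++j)
      if (sigma[i] == sigma[j]) H -= A(i, j);
  return List::create(_["sigma"] = sigma, _["H"] = H);
}
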