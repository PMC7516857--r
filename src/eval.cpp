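#include <Rcpp.h>
using namespace Rcpp;

// Fast task evaluation for the genetic algorithm. Semantics mirror
// update_brain(): sensors are clamped before each update, every gate
// reads the clamped state, written neurons take the OR of incoming gate
// outputs, unwritten sensory neurons hold their clamped value and
// unwritten non-sensory neurons decay to 0.
//
// genomes: list of integer matrices (G x 7: in1, in2, out, tt00..tt11).
// schedule: n_trials x n_updates x n_sensors clamp array (column-major).
// task_type 0: sum of output neurons at the final state must equal
// code[trial]. task_type 1: outputs must be one-hot with the 1 at
// position code[trial].
//
// Returns two scores per genome: `fitness`, the fraction of exactly
// correct trials, and `shaped`, a graded score used for selection only
// (distance of the output sum from the target code for task 0, fraction
// of matching output bits for task 1).
// [[Rcpp::export]]
List cpp_eval_population(List genomes, IntegerVector schedule,
                         int n_trials, int n_updates,
                         IntegerVector sensors,
                         IntegerVector outputs,
                         IntegerVector code, int task_type,
                         int n_neurons) {
  int n_pop = genomes.size();
  int n_sens = sensors.size();
  int n_out = outputs.size();
  NumericVector fitness(n_pop);
  NumericVector shaped(n_pop);
  std::vector<int> state(n_neurons), nxt(n_neurons);
  std::vector<char> written(n_neurons), is_sensory(n_neurons, 0);
  for (int s = 0; s < n_sens; s++) is_sensory[sensors[s]] = 1;

  for (int p = 0; p < n_pop; p++) {
    IntegerMatrix g = genomes[p];
    int n_gates = g.nrow();
    int n_correct = 0;
    double partial = 0.0;
    for (int i = 0; i < n_trials; i++) {
      std::fill(state.begin(), state.end(), 0);
      for (int u = 0; u < n_updates; u++) {
        for (int s = 0; s < n_sens; s++)
          state[sensors[s]] = schedule[i + n_trials * (u + n_updates * s)];
        std::fill(nxt.begin(), nxt.end(), 0);
        std::fill(written.begin(), written.end(), 0);
        for (int k = 0; k < n_gates; k++) {
          int idx = 2 * state[g(k, 0)] + state[g(k, 1)];
          int v = g(k, 3 + idx);
          int j = g(k, 2);
          if (v > nxt[j]) nxt[j] = v;
          written[j] = 1;
        }
        for (int j = 0; j < n_neurons; j++) {
          if (!written[j] && is_sensory[j]) nxt[j] = state[j];
        }
        std::copy(nxt.begin(), nxt.end(), state.begin());
      }
      if (task_type == 0) {
        int s = 0;
        for (int o = 0; o < n_out; o++) s += state[outputs[o]];
        if (s == code[i]) n_correct++;
        partial += 1.0 - (double)std::abs(s - code[i]) / n_out;
      } else {
        int match = 0;
        for (int o = 0; o < n_out; o++) {
          int want = (o == code[i]) ? 1 : 0;
          if (state[outputs[o]] == want) match++;
        }
        if (match == n_out) n_correct++;
        partial += (double)match / n_out;
      }
    }
    fitness[p] = (double)n_correct / n_trials;
    shaped[p] = partial / n_trials;
  }
  return List::create(Named("fitness") = fitness,
                      Named("shaped") = shaped);
}
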