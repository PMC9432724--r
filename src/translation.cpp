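// Gillespie kernel for translation of a single mRNA.
//
// State: ribosome codon positions (descending; element 0 is the leading
// ribosome, closest to the stop codon) plus a per-ribosome MTS maturity
// flag.  Events: initiation at k_init when codon 1 is free; elongation of
// each ribosome at k_elong into a free codon (1-codon footprint); a
// ribosome on codon L terminates at k_elong; in maturation mode each
// ribosome at or past codon l_MTS carries an independent exponential
// maturation clock at rate k_MTS; decay at k_decay ends the mRNA.
//
// The kernel advances the state for a bounded time window so that the
// coupled translation-diffusion simulator can interleave spatial
// first-passage events: by memorylessness the translation process can be
// stopped and restarted at region changes without bias.

#include <Rcpp.h>
using namespace Rcpp;

// stop reasons
enum { REASON_WINDOW = 0, REASON_DECAY = 1, REASON_GAIN = 2,
       REASON_LOSS = 3 };

// competence count under the active model
static inline int competent_count(const std::vector<int> &pos,
                                  const std::vector<char> &mat,
                                  int l_mts, bool maturation) {
  int n = 0;
  for (size_t i = 0; i < pos.size(); ++i) {
    if (pos[i] >= l_mts && (!maturation || mat[i])) ++n;
  }
  return n;
}

// [[Rcpp::export(name = ".advance_translation_cpp")]]
List advance_translation_cpp(IntegerVector pos0, LogicalVector mat0,
                             double k_init, double k_elong, int L,
                             int l_mts, bool maturation, double k_mts,
                             double k_decay, double window,
                             bool stop_on_gain, bool stop_on_loss,
                             bool record) {
  std::vector<int> pos(pos0.begin(), pos0.end());
  std::vector<char> mat(mat0.begin(), mat0.end());

  double t = 0.0;              // time elapsed within this window
  double t_translated = 0.0;   // time with >= 1 translated MTS
  double t_mature = 0.0;       // time with >= 1 mature MTS
  double t_competent = 0.0;    // time with >= 1 competent MTS (model-dep.)
  double int_ribo = 0.0;       // integral of ribosome count dt
  double int_translated = 0.0; // integral of translated-MTS count dt
  double int_mature = 0.0;     // integral of mature-MTS count dt
  int reason = REASON_WINDOW;
  long n_events = 0, n_terminated = 0;

  std::vector<double> log_t;
  std::vector<int> log_ev, log_nribo, log_ntrans, log_nmat;

  RNGScope rngScope;

  for (;;) {
    const int n_ribo = (int)pos.size();
    int n_trans = 0, n_mat = 0;
    for (int i = 0; i < n_ribo; ++i) {
      if (pos[i] >= l_mts) {
        ++n_trans;
        if (mat[i]) ++n_mat;
      }
    }
    const int n_comp = maturation ? n_mat : n_trans;

    // event rates
    const bool can_init = (n_ribo == 0) || (pos[n_ribo - 1] > 1);
    double rate_init = can_init ? k_init : 0.0;
    double rate_matur = 0.0;
    int n_eligible = 0;
    if (maturation) {
      for (int i = 0; i < n_ribo; ++i)
        if (pos[i] >= l_mts && !mat[i]) ++n_eligible;
      rate_matur = n_eligible * k_mts;
    }
    // elongation/termination: ribosome i moves if leading or gap > 1
    double rate_elong = 0.0;
    for (int i = 0; i < n_ribo; ++i)
      if (i == 0 || pos[i - 1] > pos[i] + 1) rate_elong += k_elong;
    const double total = rate_init + rate_elong + rate_matur + k_decay;

    double dt;
    if (total <= 0.0) {
      dt = R_PosInf;
    } else {
      dt = R::exp_rand() / total;
    }

    const double step = std::min(dt, window - t);
    if (step > 0 && R_FINITE(step)) {
      int_ribo += n_ribo * step;
      int_translated += n_trans * step;
      int_mature += n_mat * step;
      if (n_trans > 0) t_translated += step;
      if (n_mat > 0) t_mature += step;
      if (n_comp > 0) t_competent += step;
    }

    if (!R_FINITE(dt) || t + dt >= window) {
      t = window;
      reason = REASON_WINDOW;
      break;
    }
    t += dt;
    ++n_events;

    // select event
    double u = unif_rand() * total;
    int ev = -1; // 0 init, 1 elong/term, 2 maturation, 3 decay
    if (u < rate_init) {
      ev = 0;
    } else if ((u -= rate_init) < rate_elong) {
      ev = 1;
    } else if ((u -= rate_elong) < rate_matur) {
      ev = 2;
    } else {
      ev = 3;
    }

    if (ev == 0) {
      pos.push_back(1);
      mat.push_back(0);
    } else if (ev == 1) {
      // pick among movable ribosomes
      int k = (int)(u / k_elong);
      int seen = 0, idx = -1;
      for (int i = 0; i < n_ribo; ++i) {
        if (i == 0 || pos[i - 1] > pos[i] + 1) {
          if (seen == k) { idx = i; break; }
          ++seen;
        }
      }
      if (idx < 0) idx = 0; // numerical guard
      if (pos[idx] == L) {
        pos.erase(pos.begin() + idx);
        mat.erase(mat.begin() + idx);
        ++n_terminated;
      } else {
        pos[idx] += 1;
      }
    } else if (ev == 2) {
      int k = (int)(u / k_mts);
      if (k >= n_eligible) k = n_eligible - 1;
      int seen = 0;
      for (int i = 0; i < n_ribo; ++i) {
        if (pos[i] >= l_mts && !mat[i]) {
          if (seen == k) { mat[i] = 1; break; }
          ++seen;
        }
      }
    } else {
      pos.clear();
      mat.clear();
      reason = REASON_DECAY;
      break;
    }

    if (record) {
      int nt = 0, nm = 0;
      for (size_t i = 0; i < pos.size(); ++i)
        if (pos[i] >= l_mts) { ++nt; if (mat[i]) ++nm; }
      log_t.push_back(t);
      log_ev.push_back(ev);
      log_nribo.push_back((int)pos.size());
      log_ntrans.push_back(nt);
      log_nmat.push_back(nm);
    }

    // competence-crossing stops (binding/unbinding triggers)
    const int n_comp_new = competent_count(pos, mat, l_mts, maturation);
    if (stop_on_gain && n_comp == 0 && n_comp_new > 0) {
      reason = REASON_GAIN;
      break;
    }
    if (stop_on_loss && n_comp > 0 && n_comp_new == 0) {
      reason = REASON_LOSS;
      break;
    }
  }

  List out = List::create(
      _["pos"] = IntegerVector(pos.begin(), pos.end()),
      _["mature"] = LogicalVector(mat.begin(), mat.end()),
      _["elapsed"] = t, _["reason"] = reason,
      _["t_translated"] = t_translated, _["t_mature"] = t_mature,
      _["t_competent"] = t_competent, _["int_ribo"] = int_ribo,
      _["int_translated"] = int_translated, _["int_mature"] = int_mature,
      _["n_events"] = (double)n_events,
      _["n_terminated"] = (double)n_terminated);
  if (record) {
    out["log"] = DataFrame::create(
        _["time"] = NumericVector(log_t.begin(), log_t.end()),
        _["event"] = IntegerVector(log_ev.begin(), log_ev.end()),
        _["n_ribosomes"] = IntegerVector(log_nribo.begin(), log_nribo.end()),
        _["n_translated_mts"] = IntegerVector(log_ntrans.begin(),
                                              log_ntrans.end()),
        _["n_mature_mts"] = IntegerVector(log_nmat.begin(), log_nmat.end()));
  }
  return out;
}
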