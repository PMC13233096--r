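#include <Rcpp.h>
using namespace Rcpp;

// Discrete-time two-stage dynamic signal detection (2DSD) core.
//
// Evidence for target and distractor evolves as independent streams with
// per-step Normal(drift, s) increments; the decision variable is their
// difference, simulated directly as one stream with per-step increments
// Normal(delta, s*sqrt(2)) where delta = drift_target - drift_distractor
// (the per-trial drifts are still drawn per stream, Normal(nu, eta) each).
// Boundaries sit at +/- a/2 around the unbiased midpoint; the start point
// is Uniform(-s_z/2, +s_z/2). The upper boundary corresponds to choosing
// the target. After the first crossing, accumulation continues for t_pd
// further steps (added in closed form: the sum of t_pd iid normal
// increments is Normal(delta*t_pd, 2*s^2*t_pd)); confidence is the
// relative evidence in favour of the *chosen* option at decision + t_pd.
//
// Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
List dsd_core(int n, double nu_target, double nu_distractor, double eta,
              double s, double s_z, double a, double t_er, int t_pd,
              int max_steps) {
  IntegerVector choice_target(n);  // 1 = chose target (correct)
  NumericVector rt(n);             // decision step + t_er (ms)
  NumericVector conf(n);           // chosen-minus-unchosen evidence
  LogicalVector censored(n);
  const double half_a = a / 2.0;
  const double sd_step = s * std::sqrt(2.0);
  const double sd_post = (t_pd > 0) ? sd_step * std::sqrt((double)t_pd) : 0.0;

  for (int i = 0; i < n; ++i) {
    double drift_t = R::rnorm(nu_target, eta);
    double drift_d = R::rnorm(nu_distractor, eta);
    double delta = drift_t - drift_d;
    double x = (s_z > 0.0) ? R::runif(-s_z / 2.0, s_z / 2.0) : 0.0;
    int step = 0;
    int hit = 0;  // +1 upper (target), -1 lower (distractor), 0 none
    while (step < max_steps) {
      ++step;
      x += R::rnorm(delta, sd_step);
      if (x >= half_a) { hit = 1; break; }
      if (x <= -half_a) { hit = -1; break; }
    }
    if (hit == 0) {
      censored[i] = true;
      choice_target[i] = NA_INTEGER;
      rt[i] = NA_REAL;
      conf[i] = NA_REAL;
      continue;
    }
    censored[i] = false;
    choice_target[i] = (hit == 1) ? 1 : 0;
    rt[i] = step + t_er;
    double x_post = x;
    if (t_pd > 0) x_post += R::rnorm(delta * t_pd, sd_post);
    conf[i] = (hit == 1) ? x_post : -x_post;
  }
  return List::create(_["choice_target"] = choice_target, _["rt"] = rt,
                      _["conf_raw"] = conf, _["censored"] = censored);
}
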