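#include <Rcpp.h>
#include <functional>
using namespace Rcpp;

// Univariate slice sampler (Neal 2003): stepping out with unbounded
// expansion, then shrinkage. logf must be a proper (unnormalized) log
// density of the transformed variable, jacobian included.
static double slice_sample(double x0, const std::function<double(double)>& logf,
                           double w) {
  double fx0 = logf(x0);
  double logy = fx0 + std::log(R::unif_rand());
  double u = R::unif_rand();
  double L = x0 - w * u;
  double Rr = L + w;
  int guard = 0;
  while (logf(L) > logy && guard++ < 10000) L -= w;
  guard = 0;
  while (logf(Rr) > logy && guard++ < 10000) Rr += w;
  for (int it = 0; it < 10000; ++it) {
    double x1 = L + R::unif_rand() * (Rr - L);
    if (logf(x1) > logy) return x1;
    if (x1 < x0) L = x1; else Rr = x1;
  }
  return x0; // shrinkage exhausted; keep current value
}

// Collapsed Gibbs sampler for the Poisson-Beta model.
// Priors: alpha ~ Gamma(1, scale th_a), beta ~ Gamma(1, scale th_b),
// gamma ~ Gamma(1, scale th_g). Latent activities c_i in (0,1) are updated
// on the logit scale, parameters on the log scale, each by slice sampling
// with step-out width w (log/logit units).
// [[Rcpp::export]]
List pb_gibbs_cpp(IntegerVector x, int n_iter, int n_burnin, int thin,
                  double th_a, double th_b, double th_g, double w,
                  double alpha0, double beta0, double gamma0) {
  int n = x.size();
  double a = alpha0, b = beta0, g = gamma0;
  std::vector<double> c(n);
  double Sx = 0.0;
  for (int i = 0; i < n; ++i) Sx += x[i];
  for (int i = 0; i < n; ++i) {
    double ci = (x[i] + 0.5) / (g + 1.0);
    if (ci >= 1.0) ci = 0.99;
    if (ci <= 0.0) ci = 0.01;
    c[i] = ci;
  }
  int n_kept = (n_iter - n_burnin + thin - 1) / thin;
  NumericMatrix draws(n_kept, 3);
  int kept = 0;

  for (int iter = 0; iter < n_iter; ++iter) {
    // latent activities
    for (int i = 0; i < n; ++i) {
      double xi = x[i];
      auto logf = [&](double u) {
        double ci = 1.0 / (1.0 + std::exp(-u));
        if (ci <= 0.0 || ci >= 1.0) return -std::numeric_limits<double>::infinity();
        // log Beta(ci|a,b) + log Pois(xi|ci g) + logit jacobian
        return (a - 1.0) * std::log(ci) + (b - 1.0) * std::log1p(-ci)
             + xi * std::log(ci * g) - ci * g
             + std::log(ci) + std::log1p(-ci);
      };
      double u0 = std::log(c[i]) - std::log1p(-c[i]);
      double u1 = slice_sample(u0, logf, w);
      c[i] = 1.0 / (1.0 + std::exp(-u1));
    }
    double S1 = 0.0, S2 = 0.0, Sc = 0.0;
    for (int i = 0; i < n; ++i) {
      S1 += std::log(c[i]);
      S2 += std::log1p(-c[i]);
      Sc += c[i];
    }
    // alpha | c, beta
    {
      auto logf = [&](double u) {
        double av = std::exp(u);
        return -av / th_a
             + n * (R::lgammafn(av + b) - R::lgammafn(av)) + (av - 1.0) * S1
             + u; // log jacobian
      };
      a = std::exp(slice_sample(std::log(a), logf, w));
    }
    // beta | c, alpha
    {
      auto logf = [&](double u) {
        double bv = std::exp(u);
        return -bv / th_b
             + n * (R::lgammafn(a + bv) - R::lgammafn(bv)) + (bv - 1.0) * S2
             + u;
      };
      b = std::exp(slice_sample(std::log(b), logf, w));
    }
    // gamma | c
    {
      auto logf = [&](double u) {
        double gv = std::exp(u);
        return -gv / th_g + Sx * u - gv * Sc + u;
      };
      g = std::exp(slice_sample(std::log(g), logf, w));
    }
    // joint scale move along the weakly identified (gamma, c) ridge:
    // gamma' = s*gamma, c_i' = c_i/s leaves every Poisson factor invariant,
    // so the slice updates above only need to explore the remaining
    // directions. Metropolis with a log-normal multiplier.
    {
      double ls = R::norm_rand() * 0.4;
      double s_mult = std::exp(ls);
      bool ok = true;
      for (int i = 0; i < n; ++i)
        if (c[i] / s_mult >= 1.0) { ok = false; break; }
      if (ok) {
        double g_new = g * s_mult;
        double lacc = -(g_new - g) / th_g       // Exp(th_g) prior on gamma
                    + (1.0 - n) * ls            // proposal + c-transform Jacobians
                    - (a - 1.0) * n * ls;       // (alpha-1) * sum dlog(c_i)
        for (int i = 0; i < n; ++i)
          lacc += (b - 1.0) * (std::log1p(-c[i] / s_mult) - std::log1p(-c[i]));
        if (std::log(R::unif_rand()) < lacc) {
          g = g_new;
          for (int i = 0; i < n; ++i) c[i] /= s_mult;
        }
      }
    }
    // companion move for the (beta, gamma, c) ridge: beta' = s*beta,
    // gamma' = s*gamma, c_i' = c_i/s (small-duty genes have c ~ alpha/beta,
    // so shrinking c pairs with inflating beta and gamma together).
    {
      double ls = R::norm_rand() * 0.4;
      double s_mult = std::exp(ls);
      bool ok = true;
      for (int i = 0; i < n; ++i)
        if (c[i] / s_mult >= 1.0) { ok = false; break; }
      if (ok) {
        double g_new = g * s_mult, b_new = b * s_mult;
        double lacc = -(g_new - g) / th_g - (b_new - b) / th_b
                    + 2.0 * ls                 // multiplicative proposals
                    - (double)n * ls           // c-transform Jacobian
                    - (a - 1.0) * n * ls
                    + n * (R::lgammafn(a + b_new) - R::lgammafn(b_new)
                           - R::lgammafn(a + b) + R::lgammafn(b));
        for (int i = 0; i < n; ++i)
          lacc += (b_new - 1.0) * std::log1p(-c[i] / s_mult)
                - (b - 1.0) * std::log1p(-c[i]);
        if (std::log(R::unif_rand()) < lacc) {
          g = g_new; b = b_new;
          for (int i = 0; i < n; ++i) c[i] /= s_mult;
        }
      }
    }
    if (iter >= n_burnin && (iter - n_burnin) % thin == 0 && kept < n_kept) {
      draws(kept, 0) = a;
      draws(kept, 1) = b;
      draws(kept, 2) = g;
      ++kept;
    }
  }
  return List::create(_["draws"] = draws, _["latent_c"] = NumericVector(c.begin(), c.end()));
}

// Exact stochastic simulation of the two-state (telegraph) model with
// absolute rates a (on), b (off), g (transcription while on), l
// (degradation). Returns transcript counts sampled every dt over t_end
// after discarding burnin.
// [[Rcpp::export]]
IntegerVector telegraph_gillespie_cpp(double a, double b, double g, double l,
                                      double t_end, double dt, double burnin) {
  int n_samples = (int)std::floor(t_end / dt) + 1;
  IntegerVector out(n_samples);
  double t = 0.0, t_total = burnin + t_end;
  int s = (R::unif_rand() < a / (a + b)) ? 1 : 0; // stationary promoter state
  long n = 0;
  double next_sample = burnin;
  int k = 0;
  while (t < t_total && k < n_samples) {
    double r_switch = s ? b : a;
    double r_tx = s ? g : 0.0;
    double r_deg = l * (double)n;
    double rate = r_switch + r_tx + r_deg;
    double tau = R::exp_rand() / rate;
    // record samples passed during this holding time
    while (next_sample <= t + tau && k < n_samples) {
      out[k++] = (int)n;
      next_sample += dt;
    }
    t += tau;
    double u = R::unif_rand() * rate;
    if (u < r_switch) s = 1 - s;
    else if (u < r_switch + r_tx) ++n;
    else --n;
  }
  while (k < n_samples) out[k++] = (int)n;
  return out;
}
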