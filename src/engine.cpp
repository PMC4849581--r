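#include <Rcpp.h>
#include <unordered_map>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Landscape evaluation
//
// Landscapes are passed from R as a flat list:
//   type: 0 = generalized LP (k, d = 2), 1 = min over d inputs,
//         2 = polynomial x + y + (x y)^n / xi^(2n-1), 3 = product x y/(x+y),
//         4 = saturable (x/(1+x))(y/(1+y)), 5 = bilinear lookup on (ln x, ln y)
//   rotation (optional, 2-input only): angle (radians) about a center in
//   (ln x, ln y); query points are rotated back before evaluating the base map.
// ---------------------------------------------------------------------------

struct LandSpec {
  int type;
  double k, n, xi;
  // lookup grid of z values, row i = ln x index, col j = ln y index
  NumericMatrix tab;
  double lx0, dlx, ly0, dly;
  int nx, ny;
  bool clamp;
  bool rotated;
  double cosr, sinr, cx, cy;
};

static LandSpec parse_landscape(const List &land) {
  LandSpec L;
  L.type = as<int>(land["type"]);
  L.k = land.containsElementNamed("k") ? as<double>(land["k"]) : 0.0;
  L.n = land.containsElementNamed("n") ? as<double>(land["n"]) : 1.0;
  L.xi = land.containsElementNamed("xi") ? as<double>(land["xi"]) : 1.0;
  L.rotated = false;
  if (land.containsElementNamed("angle")) {
    double a = as<double>(land["angle"]);
    if (a != 0.0) {
      L.rotated = true;
      L.cosr = std::cos(-a); // inverse rotation
      L.sinr = std::sin(-a);
      NumericVector ctr = land["center"];
      L.cx = ctr[0];
      L.cy = ctr[1];
    }
  }
  if (L.type == 5) {
    L.tab = as<NumericMatrix>(land["table"]);
    L.lx0 = as<double>(land["lx0"]);
    L.dlx = as<double>(land["dlx"]);
    L.ly0 = as<double>(land["ly0"]);
    L.dly = as<double>(land["dly"]);
    L.nx = L.tab.nrow();
    L.ny = L.tab.ncol();
    L.clamp = as<bool>(land["clamp"]);
  }
  return L;
}

static inline double lp2(double x, double y, double k) {
  if (k == 0) return (x < y) ? x : y; // exact limit of the closed form
  double a = k + x + y;
  double disc = a * a - 4.0 * x * y;
  if (disc < 0) disc = 0;
  return 0.5 * (a - std::sqrt(disc));
}

static inline double lookup_z(const LandSpec &L, double lx, double ly) {
  double fx = (lx - L.lx0) / L.dlx;
  double fy = (ly - L.ly0) / L.dly;
  const double eps = 1e-8;
  if (!L.clamp && (fx < -eps || fx > L.nx - 1 + eps || fy < -eps ||
                   fy > L.ny - 1 + eps)) {
    stop("lookup query outside grid bounds");
  }
  if (fx < 0) fx = 0;
  if (fx > L.nx - 1) fx = L.nx - 1;
  if (fy < 0) fy = 0;
  if (fy > L.ny - 1) fy = L.ny - 1;
  int i = (int)fx, j = (int)fy;
  if (i >= L.nx - 1) i = L.nx - 2;
  if (j >= L.ny - 1) j = L.ny - 2;
  double u = fx - i, v = fy - j;
  return (1 - u) * (1 - v) * L.tab(i, j) + u * (1 - v) * L.tab(i + 1, j) +
         (1 - u) * v * L.tab(i, j + 1) + u * v * L.tab(i + 1, j + 1);
}

// evaluate phenotype from effective log-inputs le[0..d-1]
static inline double eval_z(const LandSpec &L, const double *le, int d) {
  double lx = le[0], ly = (d > 1) ? le[1] : le[0];
  if (L.rotated) {
    double u = lx - L.cx, v = ly - L.cy;
    lx = L.cx + L.cosr * u - L.sinr * v;
    ly = L.cy + L.sinr * u + L.cosr * v;
  }
  switch (L.type) {
  case 0:
    return lp2(std::exp(lx), std::exp(ly), L.k);
  case 1: {
    double m = le[0];
    for (int i = 1; i < d; ++i)
      if (le[i] < m) m = le[i];
    if (L.rotated) { // rotation only defined for d = 2
      m = (lx < ly) ? lx : ly;
    }
    return std::exp(m);
  }
  case 2: {
    double x = std::exp(lx), y = std::exp(ly);
    return x + y + std::pow(x * y, L.n) / std::pow(L.xi, 2.0 * L.n - 1.0);
  }
  case 3: {
    double x = std::exp(lx), y = std::exp(ly);
    return x * y / (x + y);
  }
  case 4: {
    double x = std::exp(lx), y = std::exp(ly);
    return (x / (1.0 + x)) * (y / (1.0 + y));
  }
  case 5:
    return lookup_z(L, lx, ly);
  }
  stop("unknown landscape type");
  return NA_REAL;
}

// [[Rcpp::export]]
NumericVector cpp_phenotype_log(List land, NumericMatrix log_inputs) {
  LandSpec L = parse_landscape(land);
  int n = log_inputs.nrow(), d = log_inputs.ncol();
  NumericVector out(n);
  std::vector<double> le(d);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < d; ++j) le[j] = log_inputs(i, j);
    out[i] = eval_z(L, le.data(), d);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Environmental-noise Metropolis-Hastings chain
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_env_chain(int n, double sigma_env, double sigma_step,
                            double delta0) {
  NumericVector out(n);
  double cur = delta0;
  double two_var = 2.0 * sigma_env * sigma_env;
  for (int i = 0; i < n; ++i) {
    if (sigma_step > 0 && sigma_env > 0) {
      double prop = cur + norm_rand() * sigma_step;
      double logr = (cur * cur - prop * prop) / two_var;
      if (logr >= 0 || unif_rand() < std::exp(logr)) cur = prop;
    }
    out[i] = cur;
  }
  return out;
}

static inline void env_update(double *delta, int d, double sigma_env,
                              double sigma_step) {
  if (sigma_env <= 0 || sigma_step <= 0) return;
  double two_var = 2.0 * sigma_env * sigma_env;
  for (int i = 0; i < d; ++i) {
    double prop = delta[i] + norm_rand() * sigma_step;
    double logr = (delta[i] * delta[i] - prop * prop) / two_var;
    if (logr >= 0 || unif_rand() < std::exp(logr)) delta[i] = prop;
  }
}

// ---------------------------------------------------------------------------
// Forward-time Wright-Fisher engine
//
// Diploid, non-overlapping generations. Per generation:
//   1. one MH update of the environmental perturbation per input
//   2. nominal inputs (allele sums) -> +env shift -> +dev noise -> z -> w
//   3. (snapshot if scheduled)
//   4. parents drawn by fitness-proportional rejection sampling; the two
//      parents of one offspring must be distinct individuals
//   5. transmission: chromosome chosen uniformly at locus 1, switched between
//      successive loci with probability recomb
//   6. mutation: each allele independently with probability mu; log-normal
//      step sd sigma_mu; proposals above allele_cap are rejected (allele kept)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_simulate(NumericMatrix alleles0, IntegerMatrix lineage0, List cfg,
                  List land) {
  LandSpec L = parse_landscape(land);
  const int N = as<int>(cfg["N"]);
  const int d = as<int>(cfg["d"]);
  const double mu = as<double>(cfg["mu"]);
  const double sigma_mu = as<double>(cfg["sigma_mu"]);
  const double recomb = as<double>(cfg["recomb"]);
  const double cap = as<double>(cfg["allele_cap"]);
  const double log_cap = std::log(cap);
  const long generations = (long)as<double>(cfg["generations"]);
  const long burn_in = (long)as<double>(cfg["burn_in"]);
  const long sample_every = (long)as<double>(cfg["sample_every"]);
  const double sigma_dev = as<double>(cfg["sigma_dev"]);
  const double sigma_env = as<double>(cfg["sigma_env"]);
  const double sigma_step = as<double>(cfg["sigma_step"]);
  const double s = as<double>(cfg["s"]);
  const double z_opt = as<double>(cfg["z_opt"]);
  const bool track_rarest = as<bool>(cfg["track_rarest"]);
  int next_lineage = as<int>(cfg["next_lineage"]);

  const int M = d * 2; // alleles per individual
  if (alleles0.nrow() != N || alleles0.ncol() != M)
    stop("allele matrix must be N x (2d)");

  std::vector<double> cur(N * M), nxt(N * M);
  std::vector<int> lin(N * M), lnx(N * M);
  for (int i = 0; i < N; ++i)
    for (int a = 0; a < M; ++a) {
      cur[i * M + a] = alleles0(i, a);
      lin[i * M + a] = lineage0(i, a);
    }

  std::vector<double> delta(d, 0.0);
  std::vector<double> w(N), z(N), zh(N);
  std::vector<double> xnom(N * d), xher(N * d), xeff(N * d);
  std::vector<double> le(d), lh(d);

  long n_snap = 0;
  if (sample_every > 0 && generations > burn_in)
    n_snap = (generations - burn_in) / sample_every;
  NumericMatrix snap_ind(n_snap * N, 3 * d + 4);
  NumericMatrix snap_delta(n_snap, d);
  NumericVector snap_gen(n_snap);
  long isnap = 0;

  RNGScope scope;

  for (long g = 1; g <= generations; ++g) {
    // 1. environmental chain, one update per input
    env_update(delta.data(), d, sigma_env, sigma_step);

    // 2. realize phenotypes and fitness
    double wmax = 0.0;
    for (int i = 0; i < N; ++i) {
      for (int l = 0; l < d; ++l) {
        double x = cur[i * M + 2 * l] + cur[i * M + 2 * l + 1];
        double lxh = std::log(x) + delta[l];
        lh[l] = lxh;
        le[l] = (sigma_dev > 0) ? lxh + norm_rand() * sigma_dev : lxh;
        xnom[i * d + l] = x;
        xher[i * d + l] = std::exp(lxh);
        xeff[i * d + l] = std::exp(le[l]);
      }
      z[i] = eval_z(L, le.data(), d);
      zh[i] = (sigma_dev > 0) ? eval_z(L, lh.data(), d) : z[i];
      double lz = std::log(z[i] / z_opt);
      w[i] = std::exp(-s * lz * lz);
      if (w[i] > wmax) wmax = w[i];
    }

    // 3. snapshot
    if (sample_every > 0 && g > burn_in && (g - burn_in) % sample_every == 0 &&
        isnap < n_snap) {
      snap_gen[isnap] = (double)g;
      for (int l = 0; l < d; ++l) snap_delta(isnap, l) = delta[l];
      // per-locus lineage counts for rarest-allele frequencies
      std::vector<std::unordered_map<int, int>> counts;
      if (track_rarest) {
        counts.resize(d);
        for (int l = 0; l < d; ++l)
          for (int i = 0; i < N; ++i) {
            counts[l][lin[i * M + 2 * l]]++;
            counts[l][lin[i * M + 2 * l + 1]]++;
          }
      }
      for (int i = 0; i < N; ++i) {
        long r = isnap * N + i;
        for (int l = 0; l < d; ++l) {
          snap_ind(r, l) = xnom[i * d + l];
          snap_ind(r, d + l) = xher[i * d + l];
          snap_ind(r, 2 * d + l) = xeff[i * d + l];
        }
        snap_ind(r, 3 * d) = z[i];
        snap_ind(r, 3 * d + 1) = zh[i];
        snap_ind(r, 3 * d + 2) = w[i];
        double rar = NA_REAL;
        if (track_rarest) {
          int mn = 2 * N;
          for (int l = 0; l < d; ++l) {
            int c1 = counts[l][lin[i * M + 2 * l]];
            int c2 = counts[l][lin[i * M + 2 * l + 1]];
            if (c1 < mn) mn = c1;
            if (c2 < mn) mn = c2;
          }
          rar = (double)mn / (2.0 * N);
        }
        snap_ind(r, 3 * d + 3) = rar;
      }
      ++isnap;
    }

    if (g == generations) break; // last generation is assessment-only

    if (wmax <= 0) stop("all fitness values are zero at generation %ld", g);

    // 4-5. choose parents and transmit
    for (int i = 0; i < N; ++i) {
      int p1, p2;
      do {
        p1 = (int)(unif_rand() * N);
        if (p1 >= N) p1 = N - 1;
      } while (!(w[p1] > unif_rand() * wmax));
      do {
        do {
          p2 = (int)(unif_rand() * N);
          if (p2 >= N) p2 = N - 1;
        } while (!(w[p2] > unif_rand() * wmax));
      } while (p2 == p1);
      const int par[2] = {p1, p2};
      for (int h = 0; h < 2; ++h) {
        int p = par[h];
        int chrom = (unif_rand() < 0.5) ? 0 : 1;
        for (int l = 0; l < d; ++l) {
          if (l > 0 && unif_rand() < recomb) chrom = 1 - chrom;
          nxt[i * M + 2 * l + h] = cur[p * M + 2 * l + chrom];
          lnx[i * M + 2 * l + h] = lin[p * M + 2 * l + chrom];
        }
      }
    }

    // 6. mutation (geometric skipping over the N*2d allele slots)
    if (mu > 0) {
      long total = (long)N * M;
      long idx = (long)R::rgeom(mu);
      while (idx >= 0 && idx < total) {
        double lv = std::log(nxt[idx]) + norm_rand() * sigma_mu;
        if (lv < log_cap) {
          nxt[idx] = std::exp(lv);
          lnx[idx] = next_lineage++;
        }
        idx += 1 + (long)R::rgeom(mu);
      }
    }

    cur.swap(nxt);
    lin.swap(lnx);
  }

  NumericMatrix af(N, M);
  IntegerMatrix lf(N, M);
  for (int i = 0; i < N; ++i)
    for (int a = 0; a < M; ++a) {
      af(i, a) = cur[i * M + a];
      lf(i, a) = lin[i * M + a];
    }

  return List::create(
      _["snap_gen"] = snap_gen, _["snap_delta"] = snap_delta,
      _["snap_ind"] = snap_ind, _["alleles"] = af, _["lineage"] = lf,
      _["next_lineage"] = next_lineage, _["delta"] = NumericVector(delta.begin(), delta.end()));
}
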