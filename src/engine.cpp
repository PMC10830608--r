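#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 8 compass headings, clockwise from "north" (decreasing row). Range
// expansion proceeds toward increasing row index; heading 4 ("south")
// points up-range.
static const int DR[8] = {-1, -1, 0, 1, 1,  1,  0, -1};
static const int DC[8] = { 0,  1, 1, 1, 0, -1, -1, -1};

// settlement rule codes (kept in sync with R-side settlement_rules())
enum Settle { HABITAT_ONLY = 0, MATE_SEARCH = 1, DENS_DEP = 2, MATE_SEARCH_DD = 3 };

static inline int turn_size(int from, int to) {
  int d = std::abs(from - to);
  return d > 4 ? 8 - d : d;
}

static inline double settle_prob_dd(double nf, double b, double beta_s, double alpha_s) {
  return 1.0 / (1.0 + std::exp(-(b * nf - beta_s) * alpha_s));
}

// Per-heading effective cost surface governing a step from a cell toward
// each of the 8 headings: the arithmetic mean of per-cell movement costs
// over the cells within perceptual range in that direction, truncated at
// the grid border. Two aggregations:
//   line   — the PR cells along the heading's straight line, starting at
//            the candidate (adjacent) cell;
//   sector — every cell within Euclidean distance PR whose bearing lies
//            within 22.5 degrees of the heading (a 45-degree wedge).
// [[Rcpp::export]]
NumericMatrix sms_effective_cost_cpp(IntegerVector habitat, int ncols, int nrows,
                                     double cost_hab, double cost_mat, int pr,
                                     int sector) {
  int ncells = ncols * nrows;
  NumericMatrix eff(ncells, 8);
  // offsets per heading
  std::vector< std::vector< std::pair<int,int> > > off(8);
  if (sector) {
    const double halfwidth = 22.5 * M_PI / 180.0 + 1e-9;
    for (int d = 0; d < 8; ++d) {
      double ad = std::atan2((double) DC[d], (double) -DR[d]);
      for (int dr = -pr; dr <= pr; ++dr) {
        for (int dc = -pr; dc <= pr; ++dc) {
          if (dr == 0 && dc == 0) continue;
          if (std::sqrt((double)(dr * dr + dc * dc)) > pr + 1e-9) continue;
          double a = std::atan2((double) dc, (double) -dr);
          double da = std::fabs(a - ad);
          if (da > M_PI) da = 2 * M_PI - da;
          if (da <= halfwidth) off[d].push_back(std::make_pair(dr, dc));
        }
      }
    }
  } else {
    for (int d = 0; d < 8; ++d)
      for (int k = 1; k <= pr; ++k)
        off[d].push_back(std::make_pair(k * DR[d], k * DC[d]));
  }
  for (int d = 0; d < 8; ++d) {
    for (int r = 0; r < nrows; ++r) {
      for (int c = 0; c < ncols; ++c) {
        double s = 0.0; int n = 0;
        for (size_t k = 0; k < off[d].size(); ++k) {
          int rr = r + off[d][k].first, cc = c + off[d][k].second;
          if (rr < 0 || rr >= nrows || cc < 0 || cc >= ncols) continue;
          s += habitat[rr * ncols + cc] ? cost_hab : cost_mat;
          ++n;
        }
        eff(r * ncols + c, d) = n > 0 ? s / n : cost_mat;
      }
    }
  }
  return eff;
}

struct MoveParams {
  int ncols, nrows, ncells;
  double step_mort;
  double dpw[5];          // directional persistence weights DP^(-turn)
  int settlement;
  double b, beta_s, alpha_s;
  long max_ticks;
};

struct Dispersers {
  std::vector<int> cell, sex, natal, head, steps;
  std::vector<char> status; // 0 moving, 1 settled, 2 died in transit
};

// One SMS step for disperser i: per-step mortality, then a move to a
// neighbouring on-grid cell with probability proportional to
// directional_weight(turn) / effective_cost(candidate, heading).
static inline void sms_step(Dispersers &dsp, int i, const int *habitat,
                            const NumericMatrix &inveff, const MoveParams &mp) {
  if (unif_rand() < mp.step_mort) { dsp.status[i] = 2; return; }
  int cell = dsp.cell[i];
  int r = cell / mp.ncols, c = cell % mp.ncols;
  int head = dsp.head[i];
  double w[8]; int nb[8];
  double tot = 0.0;
  for (int d = 0; d < 8; ++d) {
    int rr = r + DR[d], cc = c + DC[d];
    if (rr < 0 || rr >= mp.nrows || cc < 0 || cc >= mp.ncols) { w[d] = 0.0; nb[d] = -1; continue; }
    int cand = rr * mp.ncols + cc;
    double wd = inveff(cell, d);
    if (head >= 0) wd *= mp.dpw[turn_size(head, d)];
    w[d] = wd; nb[d] = cand;
    tot += wd;
  }
  if (tot <= 0.0) { dsp.status[i] = 2; return; } // no legal neighbour
  double u = unif_rand() * tot, acc = 0.0;
  int chosen = -1;
  for (int d = 0; d < 8; ++d) {
    acc += w[d];
    if (u <= acc && w[d] > 0.0) { chosen = d; break; }
  }
  if (chosen < 0) for (int d = 7; d >= 0; --d) if (w[d] > 0.0) { chosen = d; break; }
  dsp.cell[i] = nb[chosen];
  dsp.head[i] = chosen;
  dsp.steps[i] += 1;
}

// Synchronous dispersal scheduler: every still-moving disperser takes one
// step per global tick (uniformly random order within the tick); settlement
// is checked on each entry into a non-natal habitat cell against
// up-to-the-moment occupancy (nF/nM include residents and already-settled
// dispersers). At tick end, under mate-search rules, any non-natal habitat
// cell holding unsettled dispersers of both sexes settles them (subject to
// the density-dependent Bernoulli when combined) — simultaneous arrival.
static void run_dispersal(Dispersers &dsp, const int *habitat,
                          std::vector<int> &nF, std::vector<int> &nM,
                          const NumericMatrix &inveff, const MoveParams &mp) {
  int n = dsp.cell.size();
  std::vector<int> moving;
  moving.reserve(n);
  for (int i = 0; i < n; ++i) if (dsp.status[i] == 0) moving.push_back(i);
  bool ms = (mp.settlement == MATE_SEARCH || mp.settlement == MATE_SEARCH_DD);
  std::vector<int> movF, movM;
  if (ms) { movF.assign(mp.ncells, 0); movM.assign(mp.ncells, 0); }
  long tick = 0;
  while (!moving.empty()) {
    if (++tick > mp.max_ticks)
      stop("dispersal scheduler exceeded max_ticks (%d dispersers still in transit)",
           (int) moving.size());
    // Fisher-Yates shuffle of this tick's processing order
    for (int i = (int) moving.size() - 1; i > 0; --i) {
      int j = (int) std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(moving[i], moving[j]);
    }
    std::vector<int> still;
    still.reserve(moving.size());
    for (size_t k = 0; k < moving.size(); ++k) {
      int i = moving[k];
      sms_step(dsp, i, habitat, inveff, mp);
      if (dsp.status[i] == 2) continue;
      int cell = dsp.cell[i];
      if (habitat[cell] && cell != dsp.natal[i]) {
        bool settle = false;
        switch (mp.settlement) {
        case HABITAT_ONLY: settle = true; break;
        case MATE_SEARCH:
          settle = dsp.sex[i] == 0 ? nM[cell] > 0 : nF[cell] > 0; break;
        case DENS_DEP:
          settle = unif_rand() < settle_prob_dd(nF[cell], mp.b, mp.beta_s, mp.alpha_s); break;
        case MATE_SEARCH_DD:
          settle = (dsp.sex[i] == 0 ? nM[cell] > 0 : nF[cell] > 0) &&
                   unif_rand() < settle_prob_dd(nF[cell], mp.b, mp.beta_s, mp.alpha_s);
          break;
        }
        if (settle) {
          dsp.status[i] = 1;
          if (dsp.sex[i] == 0) ++nF[cell]; else ++nM[cell];
          continue;
        }
      }
      still.push_back(i);
    }
    if (ms && !still.empty()) {
      // simultaneous-arrival rule
      std::vector<int> touched;
      for (size_t k = 0; k < still.size(); ++k) {
        int i = still[k], cell = dsp.cell[i];
        if (habitat[cell] && cell != dsp.natal[i]) {
          if (movF[cell] == 0 && movM[cell] == 0) touched.push_back(cell);
          if (dsp.sex[i] == 0) ++movF[cell]; else ++movM[cell];
        }
      }
      std::vector<int> next;
      next.reserve(still.size());
      for (size_t k = 0; k < still.size(); ++k) {
        int i = still[k], cell = dsp.cell[i];
        bool pair = habitat[cell] && cell != dsp.natal[i] &&
                    movF[cell] > 0 && movM[cell] > 0;
        if (pair) {
          bool ok = true;
          if (mp.settlement == MATE_SEARCH_DD)
            ok = unif_rand() < settle_prob_dd(nF[cell], mp.b, mp.beta_s, mp.alpha_s);
          if (ok) {
            dsp.status[i] = 1;
            if (dsp.sex[i] == 0) ++nF[cell]; else ++nM[cell];
            continue;
          }
        }
        next.push_back(i);
      }
      for (size_t k = 0; k < touched.size(); ++k) { movF[touched[k]] = 0; movM[touched[k]] = 0; }
      moving.swap(next);
    } else {
      moving.swap(still);
    }
  }
}

static MoveParams make_move_params(List par, int ncols, int nrows) {
  MoveParams mp;
  mp.ncols = ncols; mp.nrows = nrows; mp.ncells = ncols * nrows;
  mp.step_mort = as<double>(par["step_mortality"]);
  double dp = as<double>(par["directional_persistence"]);
  for (int t = 0; t < 5; ++t) mp.dpw[t] = std::pow(dp, -t);
  mp.settlement = as<int>(par["settlement_code"]);
  mp.b = as<double>(par["b"]);
  mp.beta_s = as<double>(par["beta_s"]);
  mp.alpha_s = as<double>(par["alpha_s"]);
  mp.max_ticks = (long) as<double>(par["max_ticks"]);
  return mp;
}

// Standalone dispersal harness (unit tests, kernel experiments without a
// full simulation): residents given as per-cell female/male counts.
// [[Rcpp::export]]
List disperse_cohort_cpp(IntegerVector habitat, int ncols, int nrows, List par,
                         IntegerVector d_cell, IntegerVector d_sex, IntegerVector d_natal,
                         IntegerVector res_f, IntegerVector res_m) {
  MoveParams mp = make_move_params(par, ncols, nrows);
  NumericMatrix eff = sms_effective_cost_cpp(habitat, ncols, nrows,
                                             as<double>(par["cost_habitat"]),
                                             as<double>(par["cost_matrix"]),
                                             as<int>(par["perceptual_range"]),
                                             as<int>(par["cost_sector"]));
  NumericMatrix inveff(mp.ncells, 8);
  for (int i = 0; i < mp.ncells; ++i) for (int d = 0; d < 8; ++d) inveff(i, d) = 1.0 / eff(i, d);
  int n = d_cell.size();
  Dispersers dsp;
  dsp.cell.assign(d_cell.begin(), d_cell.end());
  dsp.sex.assign(d_sex.begin(), d_sex.end());
  dsp.natal.assign(d_natal.begin(), d_natal.end());
  dsp.head.assign(n, -1);
  dsp.steps.assign(n, 0);
  dsp.status.assign(n, 0);
  std::vector<int> nF(res_f.begin(), res_f.end()), nM(res_m.begin(), res_m.end());
  run_dispersal(dsp, INTEGER(habitat), nF, nM, inveff, mp);
  return List::create(_["status"] = IntegerVector(dsp.status.begin(), dsp.status.end()),
                      _["cell"] = IntegerVector(dsp.cell.begin(), dsp.cell.end()),
                      _["steps"] = IntegerVector(dsp.steps.begin(), dsp.steps.end()));
}

// Full annual-cycle simulation. Founders are given as parallel vectors
// (0-based cell index, sex 0=F/1=M, age in years). Returns yearly range
// series plus optional per-patch and per-disperser records.
// [[Rcpp::export]]
List sim_run_cpp(IntegerVector habitat, int ncols, int nrows,
                 IntegerVector f_cell, IntegerVector f_sex, IntegerVector f_age,
                 List par, int years, int core_rows,
                 bool record_patches, bool record_dispersal) {
  int ncells = ncols * nrows;
  const int *hab = INTEGER(habitat);
  MoveParams mp = make_move_params(par, ncols, nrows);

  double b = as<double>(par["b"]);
  double phi_eff = as<double>(par["phi_eff"]);
  double sexratio_f = as<double>(par["sex_ratio_f"]);
  double harem = as<double>(par["harem"]);
  bool female_only = as<bool>(par["female_only"]);
  double s0j = as<double>(par["sigma0_juv"]);
  double s0a = as<double>(par["sigma0_adult"]);
  double emig = as<double>(par["emigration_prob"]);
  int max_age = as<int>(par["max_age"]);
  bool surv_all_f = as<bool>(par["survival_all_females"]);
  bool breed_juv = as<bool>(par["breeding_includes_juveniles"]);

  NumericMatrix eff = sms_effective_cost_cpp(habitat, ncols, nrows,
                                             as<double>(par["cost_habitat"]),
                                             as<double>(par["cost_matrix"]),
                                             as<int>(par["perceptual_range"]),
                                             as<int>(par["cost_sector"]));
  NumericMatrix inveff(ncells, 8);
  for (int i = 0; i < ncells; ++i) for (int d = 0; d < 8; ++d) inveff(i, d) = 1.0 / eff(i, d);

  int core_hab = 0;
  for (int cell = 0; cell < ncells; ++cell)
    if (hab[cell] && cell / ncols < core_rows) ++core_hab;

  // individual state
  std::vector<int> icell(f_cell.begin(), f_cell.end());
  std::vector<int> isex(f_sex.begin(), f_sex.end());
  std::vector<int> iage(f_age.begin(), f_age.end());

  // per-cell scratch
  std::vector<int> adF(ncells, 0), adM(ncells, 0);
  std::vector<double> prv(ncells, 0.0);
  std::vector<int> unmated(ncells, 0), reproF(ncells, 0);
  std::vector<int> nF(ncells, 0), nM(ncells, 0);
  std::vector<int> eJF(ncells, 0), eJM(ncells, 0), eAF(ncells, 0), eAM(ncells, 0);

  // yearly series
  std::vector<int> y_year, y_n, y_edge, y_breed;
  std::vector<double> y_occ;

  // patch records
  std::vector<int> p_year, p_cell, p_adf, p_adm, p_unm, p_rep, p_ejf, p_ejm, p_eaf, p_eam;
  // dispersal records
  std::vector<int> g_year, g_sex, g_natal, g_fate, g_scell, g_steps;

  // census of current individual list into end-of-year per-cell stage counts,
  // and record yearly metrics
  std::vector<int> occ_cells;
  auto census = [&](int year) {
    occ_cells.clear();
    for (size_t i = 0; i < icell.size(); ++i) {
      int cell = icell[i];
      if (eJF[cell] + eJM[cell] + eAF[cell] + eAM[cell] == 0) occ_cells.push_back(cell);
      if (iage[i] == 0) { if (isex[i] == 0) ++eJF[cell]; else ++eJM[cell]; }
      else              { if (isex[i] == 0) ++eAF[cell]; else ++eAM[cell]; }
    }
    int edge = -1, nbreed = 0, core_breed = 0;
    for (size_t k = 0; k < occ_cells.size(); ++k) {
      int cell = occ_cells[k];
      int f = eAF[cell] + (breed_juv ? eJF[cell] : 0);
      int m = eAM[cell] + (breed_juv ? eJM[cell] : 0);
      bool breeding = female_only ? f >= 1 : (f >= 1 && m >= 1);
      if (breeding) {
        ++nbreed;
        int row = cell / ncols;
        if (row > edge) edge = row;
        if (row < core_rows) ++core_breed;
      }
    }
    y_year.push_back(year);
    y_n.push_back((int) icell.size());
    y_edge.push_back(edge);
    y_breed.push_back(nbreed);
    y_occ.push_back(core_hab > 0 ? (double) core_breed / core_hab : 0.0);
  };

  census(0); // initial state
  for (size_t k = 0; k < occ_cells.size(); ++k) {
    int cell = occ_cells[k];
    eJF[cell] = eJM[cell] = eAF[cell] = eAM[cell] = 0;
  }

  int extinct_year = -1;
  for (int year = 1; year <= years; ++year) {
    if (icell.empty()) { if (extinct_year < 0) extinct_year = year - 1; break; }

    // --- mating + reproduction ------------------------------------------
    std::vector<int> touched;
    for (size_t i = 0; i < icell.size(); ++i) {
      if (iage[i] >= 1) {
        int cell = icell[i];
        if (adF[cell] == 0 && adM[cell] == 0) touched.push_back(cell);
        if (isex[i] == 0) ++adF[cell]; else ++adM[cell];
      }
    }
    for (size_t k = 0; k < touched.size(); ++k) {
      int cell = touched[k];
      double f = adF[cell], m = adM[cell];
      if (f == 0) { prv[cell] = 0.0; continue; }
      if (female_only) { prv[cell] = 1.0; continue; }
      double hm = harem * m;
      double c = std::min(1.0, 2.0 * hm / (f + hm)) * f; // harmonic-mean mating function
      prv[cell] = c / f;
    }
    std::vector<int> b_cell, b_sex; // newborns
    for (size_t i = 0; i < icell.size(); ++i) {
      if (iage[i] >= 1 && isex[i] == 0) {
        int cell = icell[i];
        if (unif_rand() < prv[cell]) {
          ++reproF[cell];
          int litter = (int) R::rpois(phi_eff);
          for (int k = 0; k < litter; ++k) {
            b_cell.push_back(cell);
            b_sex.push_back(female_only ? 0 : (unif_rand() < sexratio_f ? 0 : 1));
          }
        } else {
          ++unmated[cell];
        }
      }
    }

    // --- juvenile emigration --------------------------------------------
    Dispersers dsp;
    for (size_t k = 0; k < b_cell.size(); ++k) {
      if (unif_rand() < emig) {
        dsp.cell.push_back(b_cell[k]);
        dsp.sex.push_back(b_sex[k]);
        dsp.natal.push_back(b_cell[k]);
      } else {
        icell.push_back(b_cell[k]);
        isex.push_back(b_sex[k]);
        iage.push_back(0);
      }
    }
    int nd = (int) dsp.cell.size();
    dsp.head.assign(nd, -1);
    dsp.steps.assign(nd, 0);
    dsp.status.assign(nd, 0);

    // --- dispersal -------------------------------------------------------
    std::fill(nF.begin(), nF.end(), 0);
    std::fill(nM.begin(), nM.end(), 0);
    for (size_t i = 0; i < icell.size(); ++i) {
      if (isex[i] == 0) ++nF[icell[i]]; else ++nM[icell[i]];
    }
    if (nd > 0) run_dispersal(dsp, hab, nF, nM, inveff, mp);
    for (int i = 0; i < nd; ++i) {
      if (dsp.status[i] == 1) {
        icell.push_back(dsp.cell[i]);
        isex.push_back(dsp.sex[i]);
        iage.push_back(0);
      }
      if (record_dispersal) {
        g_year.push_back(year);
        g_sex.push_back(dsp.sex[i]);
        g_natal.push_back(dsp.natal[i]);
        g_fate.push_back(dsp.status[i] == 1 ? 1 : 0);
        g_scell.push_back(dsp.status[i] == 1 ? dsp.cell[i] : -1);
        g_steps.push_back(dsp.steps[i]);
      }
    }

    // --- density-dependent survival + aging ------------------------------
    // nF currently counts all females in their end-of-dispersal patch;
    // optionally restrict density to adult females.
    if (!surv_all_f) {
      std::fill(nF.begin(), nF.end(), 0);
      for (size_t i = 0; i < icell.size(); ++i)
        if (isex[i] == 0 && iage[i] >= 1) ++nF[icell[i]];
    }
    {
      size_t w = 0;
      for (size_t i = 0; i < icell.size(); ++i) {
        int cell = icell[i];
        double s0 = iage[i] == 0 ? s0j : s0a;
        double sigma = s0 * std::exp(-b * nF[cell]);
        if (unif_rand() < sigma && iage[i] + 1 <= max_age) {
          icell[w] = cell; isex[w] = isex[i]; iage[w] = iage[i] + 1;
          ++w;
        }
      }
      icell.resize(w); isex.resize(w); iage.resize(w);
    }

    // --- census ----------------------------------------------------------
    census(year);
    if (record_patches) {
      // union of cells active at mating or occupied at year end
      std::vector<int> cells(occ_cells);
      for (size_t k = 0; k < touched.size(); ++k) {
        int cell = touched[k];
        if (eJF[cell] + eJM[cell] + eAF[cell] + eAM[cell] == 0 &&
            adF[cell] + adM[cell] > 0) cells.push_back(cell);
      }
      for (size_t k = 0; k < cells.size(); ++k) {
        int cell = cells[k];
        p_year.push_back(year); p_cell.push_back(cell);
        p_adf.push_back(adF[cell]); p_adm.push_back(adM[cell]);
        p_unm.push_back(unmated[cell]); p_rep.push_back(reproF[cell]);
        p_ejf.push_back(eJF[cell]); p_ejm.push_back(eJM[cell]);
        p_eaf.push_back(eAF[cell]); p_eam.push_back(eAM[cell]);
      }
    }
    // reset per-cell scratch touched this year
    for (size_t k = 0; k < touched.size(); ++k) {
      int cell = touched[k];
      adF[cell] = adM[cell] = unmated[cell] = reproF[cell] = 0;
      prv[cell] = 0.0;
    }
    for (size_t k = 0; k < occ_cells.size(); ++k) {
      int cell = occ_cells[k];
      eJF[cell] = eJM[cell] = eAF[cell] = eAM[cell] = 0;
    }
    if (icell.empty() && extinct_year < 0) extinct_year = year;
    Rcpp::checkUserInterrupt();
  }

  DataFrame yearly = DataFrame::create(
    _["year"] = IntegerVector(y_year.begin(), y_year.end()),
    _["n_individuals"] = IntegerVector(y_n.begin(), y_n.end()),
    _["edge_row"] = IntegerVector(y_edge.begin(), y_edge.end()),
    _["n_breeding_patches"] = IntegerVector(y_breed.begin(), y_breed.end()),
    _["core_occupancy"] = NumericVector(y_occ.begin(), y_occ.end()));

  List out = List::create(
    _["yearly"] = yearly,
    _["extinct"] = extinct_year >= 0,
    _["extinction_year"] = extinct_year >= 0 ? extinct_year : NA_INTEGER);
  if (record_patches)
    out["patches"] = DataFrame::create(
      _["year"] = IntegerVector(p_year.begin(), p_year.end()),
      _["cell"] = IntegerVector(p_cell.begin(), p_cell.end()),
      _["n_adult_f"] = IntegerVector(p_adf.begin(), p_adf.end()),
      _["n_adult_m"] = IntegerVector(p_adm.begin(), p_adm.end()),
      _["n_unmated_f"] = IntegerVector(p_unm.begin(), p_unm.end()),
      _["n_reproducing_f"] = IntegerVector(p_rep.begin(), p_rep.end()),
      _["end_juv_f"] = IntegerVector(p_ejf.begin(), p_ejf.end()),
      _["end_juv_m"] = IntegerVector(p_ejm.begin(), p_ejm.end()),
      _["end_adult_f"] = IntegerVector(p_eaf.begin(), p_eaf.end()),
      _["end_adult_m"] = IntegerVector(p_eam.begin(), p_eam.end()));
  if (record_dispersal)
    out["dispersal"] = DataFrame::create(
      _["year"] = IntegerVector(g_year.begin(), g_year.end()),
      _["sex"] = IntegerVector(g_sex.begin(), g_sex.end()),
      _["natal_cell"] = IntegerVector(g_natal.begin(), g_natal.end()),
      _["settled"] = IntegerVector(g_fate.begin(), g_fate.end()),
      _["settle_cell"] = IntegerVector(g_scell.begin(), g_scell.end()),
      _["steps"] = IntegerVector(g_steps.begin(), g_steps.end()));
  return out;
}
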