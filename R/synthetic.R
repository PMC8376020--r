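#' Configuration for the synthetic watershed generator
#'
#' Bundles every knob of the generator. Defaults emulate the structure of a
#' semiarid synoptic survey: ~200 sites spanning ~0.1-2000 km2 of nested
#' subwatershed area in four land-use/hydrology categories, three seasonal
#' sampling events, six solutes, planted point sources strong enough to
#' create >100%-leverage (critical source) sites, an hourglass spatial
#' variance profile, and solute-specific rank persistence (high for the
#' conservative ions Cl and SO4, lower for reactive nutrients).
#'
#' @param seed Integer seed; the generator is fully deterministic given
#'   `(seed, config)`.
#' @param n_sites Approximate total number of sites (trees are grown in
#'   whole bifurcations, so realised counts can differ by a few).
#' @param area_range_km2 Range of subwatershed areas; leaves are drawn
#'   log-uniformly up to `area_range_km2[2] / 8` so that network outlets
#'   (sums of their leaves) land near the upper end.
#' @param category_weights Named proportions of sites per category
#'   (must sum to 1).
#' @param solute_params Tibble of per-solute generator parameters; see
#'   [default_solute_params()].
#' @param season_factors Named multipliers on concentration per season.
#' @param noise_sd_log Global multiplier on the per-solute season-level
#'   lognormal noise sd. Default 1.
#' @param point_source_fraction Fraction of network sites planted as point
#'   sources. Default 0.12.
#' @param point_source_strength Point-source load in units of the network's
#'   expected baseline flux (per planted site).
#' @param persistence_mode `"persistent"` (default) keeps all site-level
#'   structure (random effects, point sources, hourglass heterogeneity)
#'   fixed across seasons so spatial rankings persist; `"scrambled"` is the
#'   rank-null mode: each season's concentrations are reassigned to random
#'   sites within their network, destroying cross-season rank structure
#'   while preserving each network's concentration distribution.
#' @param hourglass Inject extra variance at small (`< hourglass_knees[1]`)
#'   and large (`> hourglass_knees[2]`) subwatershed areas? Default `TRUE`.
#' @param hourglass_knees Area knees (km2) for the hourglass terms.
#' @param hourglass_sd Log-sds of the extra hourglass variance, length 2:
#'   small-area (headwater heterogeneity) and large-area (tailwater return
#'   flows, losing reaches and diversions).
#' @param conservative_routing If `TRUE`, internal-node concentrations are
#'   exact flux-weighted means of their children under uniform specific
#'   discharge (retention forced to 0 and no post-routing perturbations), so
#'   leverage over each network's leaves sums to exactly zero. If `FALSE`
#'   (default), per-solute in-network retention applies - which is what
#'   makes >100% leverage possible at all.
#' @return A validated `watershed_config`.
#' @export
watershed_config <- function(seed = 1L,
                             n_sites = 200L,
                             area_range_km2 = c(0.1, 2000),
                             category_weights = c(
                               AgriculturalUnregulated = 0.17,
                               MixedDammed = 0.44,
                               MountainUrban = 0.18,
                               ValleyTributaries = 0.21),
                             solute_params = default_solute_params(),
                             season_factors = c(Spring = 1.2, Summer = 0.95,
                                                Fall = 0.9),
                             noise_sd_log = 1,
                             point_source_fraction = 0.12,
                             point_source_strength = 1.5,
                             persistence_mode = c("persistent", "scrambled"),
                             hourglass = TRUE,
                             hourglass_knees = c(1, 200),
                             hourglass_sd = c(0.5, 0.8),
                             conservative_routing = FALSE) {
  persistence_mode <- match.arg(persistence_mode)
  stopifnot(
    n_sites >= 8L,
    length(area_range_km2) == 2L, all(area_range_km2 > 0),
    area_range_km2[1] < area_range_km2[2],
    point_source_fraction >= 0, point_source_fraction <= 1,
    point_source_strength >= 0,
    noise_sd_log >= 0,
    all(solute_params$baseline > 0))
  if (!setequal(names(category_weights), watershed_categories()) ||
      any(category_weights < 0) || sum(category_weights) == 0) {
    stop("watershed_config: category_weights must cover the four categories",
         call. = FALSE)
  }
  category_weights <- category_weights / sum(category_weights)
  if (!setequal(names(season_factors), watershed_seasons()) ||
      any(season_factors <= 0)) {
    stop("watershed_config: season_factors must cover the three seasons",
         call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), n_sites = as.integer(n_sites),
         area_range_km2 = area_range_km2,
         category_weights = category_weights[watershed_categories()],
         solute_params = solute_params,
         season_factors = season_factors[watershed_seasons()],
         noise_sd_log = noise_sd_log,
         point_source_fraction = point_source_fraction,
         point_source_strength = point_source_strength,
         persistence_mode = persistence_mode,
         hourglass = hourglass,
         hourglass_knees = hourglass_knees,
         hourglass_sd = hourglass_sd,
         conservative_routing = conservative_routing),
    class = "watershed_config")
}

#' Default per-solute generator parameters
#'
#' Baselines are realistic stream concentrations (mg/L) for a semiarid
#' mixed-use watershed. Land-cover coefficients act on the log scale per
#' unit fraction; impervious cover raises every solute except DOC (which
#' responds to forest cover instead). `eta_sd` is the site-level random
#' effect (shared across seasons in persistent mode) and `eps_sd` the
#' season-level noise: their ratio sets each solute's rank persistence tier
#' (conservative ions Cl/SO4 high, DOC/PO4 low). `retention` is the total
#' in-network removal, along an average leaf-to-outlet path, of
#' concentration *excess* above the diffuse landscape signal (converted
#' internally to a per-mixing-node rate from each network's mean leaf
#' depth). The diffuse signal itself routes conservatively - lateral inputs
#' keep ambient concentrations stationary downstream - while point-source
#' spikes decay in transit through uptake, sorption, losing reaches and
#' diversions. Retention of excess is near-complete for TDN and PO4 (which
#' is what lets upstream point sources exceed 100% leverage), lower for DIN
#' (so surviving loads inflate outlet DIN flux and few sites exceed 100%),
#' and 0 for the conservative ions. `point_source` marks the solutes
#' carried by planted point sources (wastewater-like: N and P species).
#'
#' @return A tibble with one row per solute.
#' @export
default_solute_params <- function() {
  tibble::tribble(
    ~solute, ~baseline, ~coef_forest, ~coef_developed, ~coef_impervious,
    ~coef_herbaceous, ~eta_sd, ~eps_sd, ~retention, ~point_source,
    "DOC", 3.5,  0.40, 0.0, 0.0, 0.0, 0.40, 0.28, 0.85, FALSE,
    "TDN", 1.0,  0.00, 0.8, 2.0, 0.0, 0.40, 0.18, 0.98, TRUE,
    "DIN", 0.6,  0.00, 0.8, 2.2, 0.0, 0.40, 0.18, 0.80, TRUE,
    "PO4", 0.05, 0.00, 0.5, 2.0, 0.0, 0.40, 0.28, 0.985, TRUE,
    "Cl",  50,   0.00, 0.5, 1.5, 0.8, 0.40, 0.10, 0.00, FALSE,
    "SO4", 40,   0.00, 0.3, 1.0, 0.8, 0.40, 0.10, 0.00, FALSE)
}

# Network layout: names, category, and share of the category's sites.
network_layout <- function() {
  tibble::tribble(
    ~network, ~category, ~share,
    "SpanishFork",   "AgriculturalUnregulated", 1.0,
    "Provo",         "MixedDammed",             1.0,
    "AmericanFork",  "MountainUrban",           0.5,
    "HobbleCreek",   "MountainUrban",           0.5,
    "BenjaminSlough", "ValleyTributaries",      0.45,
    "MillRace",      "ValleyTributaries",       0.15,
    "DryCreek",      "ValleyTributaries",       0.15,
    "GoshenValley",  "ValleyTributaries",       0.25)
}

# Mean land-cover fractions per category (forest, herbaceous, developed).
category_land_profiles <- function() {
  list(
    AgriculturalUnregulated = c(forest = 0.56, herbaceous = 0.10,
                                developed = 0.04),
    MixedDammed = c(forest = 0.65, herbaceous = 0.06, developed = 0.06),
    MountainUrban = c(forest = 0.62, herbaceous = 0.07, developed = 0.05),
    ValleyTributaries = c(forest = 0.38, herbaceous = 0.08,
                          developed = 0.22))
}

# Dirichlet-like land-cover draw for one category: normalised gammas around
# the profile; impervious is a sub-fraction of developed.
draw_land_cover <- function(category, n) {
  prof <- category_land_profiles()[[category]]
  conc <- 25
  g <- cbind(stats::rgamma(n, prof["forest"] * conc),
             stats::rgamma(n, prof["herbaceous"] * conc),
             stats::rgamma(n, prof["developed"] * conc),
             stats::rgamma(n, (1 - sum(prof)) * conc))
  frac <- g / rowSums(g)
  tibble::tibble(
    forest = frac[, 1],
    herbaceous = frac[, 2],
    developed = frac[, 3],
    impervious = frac[, 3] * stats::rbeta(n, 8, 12))
}

# Grow one random recursive bifurcation tree with n_nodes nodes (rounded to
# the nearest odd count). Returns a data frame: node id, parent, is_leaf,
# depth.
grow_tree <- function(n_nodes) {
  n_nodes <- max(3L, if (n_nodes %% 2L == 0L) n_nodes + 1L else n_nodes)
  parent <- c(NA_integer_, rep(NA_integer_, n_nodes - 1L))
  depth <- c(0L, rep(NA_integer_, n_nodes - 1L))
  is_leaf <- c(TRUE, rep(NA, n_nodes - 1L))
  used <- 1L
  while (used < n_nodes) {
    leaves <- which(is_leaf[seq_len(used)])
    split_node <- if (length(leaves) == 1L) leaves else
      leaves[sample.int(length(leaves), 1L)]
    children <- used + 1:2
    parent[children] <- split_node
    depth[children] <- depth[split_node] + 1L
    is_leaf[children] <- TRUE
    is_leaf[split_node] <- FALSE
    used <- used + 2L
  }
  data.frame(node = seq_len(n_nodes), parent = parent,
             is_leaf = is_leaf, depth = depth)
}

#' Generate the site skeleton and tree topology of a synthetic watershed
#'
#' Each non-valley network is a random recursive bifurcation tree: leaf
#' areas are drawn log-uniformly, internal areas are strictly the sums of
#' their children's (so an outlet's area equals the sum of its network's
#' leaf areas), and the root is the flagged outlet. Valley-tributary
#' networks are generated as disjoint small site sets with no shared outlet,
#' mirroring streams that discharge directly into the lake. Land-cover
#' fractions are drawn per category around realistic profiles. Deterministic
#' under `config$seed`.
#'
#' @param config A [watershed_config()].
#' @return A `watershed_skeleton`: list with `sites` (a tibble: `site_id`,
#'   `network`, `category`, `area_km2`, land cover, `is_outlet`, `is_leaf`,
#'   `parent`, `depth`) and `config`.
#' @export
generate_network <- function(config) {
  stopifnot(inherits(config, "watershed_config"))
  withr::local_seed(config$seed)
  layout <- network_layout()
  cat_n <- round(config$category_weights * config$n_sites)
  if (all(cat_n == 0)) stop("infeasible config: no sites to generate",
                            call. = FALSE)
  leaf_max <- config$area_range_km2[2] / 8
  amin <- config$area_range_km2[1]

  per_network <- lapply(seq_len(nrow(layout)), function(i) {
    net <- layout$network[i]
    cat <- layout$category[i]
    n_net <- max(ifelse(cat == "ValleyTributaries", 2L, 5L),
                 round(cat_n[[cat]] * layout$share[i]))
    prefix <- toupper(substr(gsub("[a-z]", "", net), 1, 2))
    if (cat == "ValleyTributaries") {
      # disjoint small groundwater-fed networks; no convergent outlet
      areas <- exp(stats::runif(n_net, log(amin * 2), log(100)))
      tibble::tibble(
        site_id = sprintf("%s-%03d", prefix, seq_len(n_net)),
        network = net, category = cat,
        area_km2 = areas, is_outlet = FALSE, is_leaf = TRUE,
        parent = NA_character_, depth = 0L)
    } else {
      tree <- grow_tree(n_net)
      n_leaf <- sum(tree$is_leaf)
      leaf_areas <- exp(stats::runif(n_leaf, log(amin), log(leaf_max)))
      area <- numeric(nrow(tree))
      area[tree$is_leaf] <- leaf_areas
      # accumulate leaf areas bottom-up (children always have higher ids)
      for (nd in rev(seq_len(nrow(tree)))) {
        p <- tree$parent[nd]
        if (!is.na(p)) area[p] <- area[p] + area[nd]
      }
      ids <- sprintf("%s-%03d", prefix, tree$node)
      tibble::tibble(
        site_id = ids,
        network = net, category = cat,
        area_km2 = area,
        is_outlet = tree$node == 1L,
        is_leaf = tree$is_leaf,
        parent = ifelse(is.na(tree$parent), NA_character_,
                        ids[tree$parent]),
        depth = tree$depth)
    }
  })
  sites <- dplyr::bind_rows(per_network)
  lc <- dplyr::bind_rows(lapply(split(seq_len(nrow(sites)), sites$category),
                                function(rows) {
    out <- draw_land_cover(sites$category[rows[1]], length(rows))
    out$row <- rows
    out
  }))
  lc <- lc[order(lc$row), ]
  sites$forest <- lc$forest
  sites$developed <- lc$developed
  sites$impervious <- lc$impervious
  sites$herbaceous <- lc$herbaceous
  structure(list(sites = sites, config = config),
            class = "watershed_skeleton")
}

#' @export
print.watershed_skeleton <- function(x, ...) {
  cat(sprintf(
    "<watershed_skeleton> %d sites in %d networks (%d leaves, %d outlets)\n",
    nrow(x$sites), length(unique(x$sites$network)),
    sum(x$sites$is_leaf), sum(x$sites$is_outlet)))
  invisible(x)
}

#' Generate solute concentrations on a watershed skeleton
#'
#' Leaf concentrations are lognormal around a land-cover-driven baseline:
#' `conc = baseline * season_factor * exp(sum(coef * land_cover)) *
#' exp(eta_site) * exp(eps_site_season)`, where `eta` is a site-level
#' random effect and `eps` is season-level noise; in `"scrambled"` mode
#' each season's finished concentrations are additionally permuted across
#' sites within their network (a rank-null). Routing up each tree uses
#' flux-weighted mixing under uniform specific discharge: the diffuse
#' signal mixes conservatively, while point-source excess decays at the
#' solute's in-network retention rate (exact mass balance when
#' `conservative_routing = TRUE`, which disables retention and planting).
#' Point-source loads are planted at a fraction of deeper-than-median
#' leaves for the point-source solutes; the hourglass option injects extra
#' site-level variance at the smallest leaves (pre-routing) and, when
#' routing is non-conservative, at the largest non-outlet sites
#' (post-routing). Deterministic under `config$seed`.
#'
#' @param skeleton A [generate_network()] result.
#' @param config Optional override of `skeleton$config`.
#' @return A list: `table` (a validated `site_table`, one row per site x
#'   season) and `truth` (planted source sites, planted variance boundary,
#'   true predictor subsets per solute, expected rank-persistence share per
#'   solute).
#' @export
generate_concentrations <- function(skeleton, config = skeleton$config) {
  stopifnot(inherits(skeleton, "watershed_skeleton"))
  withr::local_seed(config$seed + 1L)
  sites <- skeleton$sites
  sp <- config$solute_params
  seasons <- watershed_seasons()
  n <- nrow(sites)
  conservative <- config$conservative_routing

  # planted point sources: per non-valley network, the configured fraction
  # of sites, chosen among deeper-than-median leaves (outfalls on headwater
  # tributaries, whose loads are substantially removed before the outlet -
  # the configuration under which a source can exceed 100% leverage)
  planted <- character()
  if (!conservative && config$point_source_fraction > 0) {
    for (net in unique(sites$network[sites$category != "ValleyTributaries"])) {
      rows <- which(sites$network == net)
      m <- round(config$point_source_fraction * length(rows))
      if (m == 0L) next
      leaves <- rows[sites$is_leaf[rows]]
      deep <- leaves[sites$depth[leaves] >=
                       stats::median(sites$depth[leaves])]
      pool <- if (length(deep) >= m) deep else leaves
      planted <- c(planted,
                   sites$site_id[pool[sample.int(length(pool), min(m, length(pool)))]])
    }
  }
  # convert each solute's total in-network retention to a per-node rate via
  # the network's mean leaf depth
  mean_leaf_depth <- vapply(split(sites$depth[sites$is_leaf],
                                  sites$network[sites$is_leaf]),
                            mean, numeric(1))
  net_depth <- pmax(mean_leaf_depth[sites$network], 1)

  # children lists for routing
  kids <- split(seq_len(n), match(sites$parent, sites$site_id))
  kids_of <- vector("list", n)
  kids_of[as.integer(names(kids))] <- kids
  route_order <- order(-sites$depth)

  conc_cols <- list()
  for (si in seq_len(nrow(sp))) {
    s <- sp[si, ]
    lc_term <- s$coef_forest * sites$forest +
      s$coef_developed * sites$developed +
      s$coef_impervious * sites$impervious +
      s$coef_herbaceous * sites$herbaceous
    eta <- stats::rnorm(n, 0, s$eta_sd)
    r_node <- if (conservative || s$retention == 0) rep(0, n) else
      1 - (1 - s$retention)^(1 / net_depth)
    plant_here <- s$point_source && length(planted) > 0L
    load <- if (plant_here) {
      # load per planted site, in flux units (mg/L * km2), scaled to each
      # network's expected baseline flux; the site-level jitter is drawn
      # once (point sources are spatially fixed)
      root_area <- stats::ave(sites$area_km2, sites$network,
                              FUN = function(a) max(a))
      config$point_source_strength * s$baseline * root_area *
        exp(stats::rnorm(n, 0, 0.2))
    }
    # hourglass terms are site-level (spatial heterogeneity, not temporal):
    # drawn once, reused across seasons
    hg_sd <- rep_len(config$hourglass_sd, 2L)
    hg_small <- if (config$hourglass) {
      ifelse(sites$is_leaf & sites$area_km2 < config$hourglass_knees[1],
             stats::rnorm(n, 0, hg_sd[1]), 0)
    } else 0
    hg_big <- if (config$hourglass && !conservative) {
      ifelse(sites$area_km2 > config$hourglass_knees[2] & !sites$is_outlet,
             stats::rnorm(n, 0, hg_sd[2]), 0)
    } else 0

    for (season in seasons) {
      eps <- stats::rnorm(n, 0, s$eps_sd * config$noise_sd_log)
      diffuse <- s$baseline * config$season_factors[[season]] *
        exp(lc_term + eta + eps + hg_small)
      excess <- numeric(n)
      if (plant_here) {
        hit <- sites$site_id %in% planted
        excess[hit] <- load[hit] / pmax(sites$area_km2[hit], 1e-6)
      }
      # route up the trees under uniform specific discharge: the diffuse
      # landscape signal mixes conservatively (lateral inputs keep ambient
      # concentrations stationary), point-source excess mixes with retention
      for (nd in route_order) {
        ch <- kids_of[[nd]]
        if (is.null(ch)) next
        w <- sites$area_km2[ch] / sum(sites$area_km2[ch])
        diffuse[nd] <- sum(diffuse[ch] * w)
        excess[nd] <- (1 - r_node[nd]) * sum(excess[ch] * w)
      }
      conc <- diffuse + excess
      # large-area heterogeneity (return flows, diversions) is applied to
      # observed non-outlet concentrations after routing
      conc <- conc * exp(hg_big)
      if (config$persistence_mode == "scrambled") {
        # rank-null mode: reassign each season's concentrations to random
        # sites within the network, destroying cross-season rank structure
        # while preserving each network's concentration distribution
        for (net_rows in split(seq_len(n), sites$network)) {
          if (length(net_rows) > 1L) conc[net_rows] <- conc[sample(net_rows)]
        }
      }
      conc_cols[[paste(s$solute, season, sep = ".")]] <- conc
    }
  }

  long <- dplyr::bind_rows(lapply(seasons, function(season) {
    out <- sites[, c("site_id", "network", "category", "area_km2",
                     land_cover_classes(), "is_outlet")]
    out$season <- season
    for (si in sp$solute) {
      out[[si]] <- conc_cols[[paste(si, season, sep = ".")]]
    }
    out
  }))
  table <- as_site_table(long, solutes = sp$solute)

  truth <- list(
    planted_source_sites = sort(planted),
    planted_variance_boundary_km2 = NULL,
    true_predictor_subsets = stats::setNames(lapply(seq_len(nrow(sp)),
      function(si) {
        coefs <- c(forest = sp$coef_forest[si], developed = sp$coef_developed[si],
                   impervious = sp$coef_impervious[si],
                   herbaceous = sp$coef_herbaceous[si])
        c("season", names(coefs)[coefs != 0])
      }), sp$solute),
    true_rank_share = stats::setNames(
      sp$eta_sd^2 / (sp$eta_sd^2 + (sp$eps_sd * config$noise_sd_log)^2),
      sp$solute))
  list(table = table, truth = truth)
}

#' Generate a complete synthetic watershed survey
#'
#' Convenience wrapper: [generate_network()] then
#' [generate_concentrations()].
#'
#' @param config A [watershed_config()].
#' @return List with `table`, `truth`, `skeleton`, `config`.
#' @export
simulate_watershed <- function(config = watershed_config()) {
  skeleton <- generate_network(config)
  gen <- generate_concentrations(skeleton, config)
  list(table = gen$table, truth = gen$truth, skeleton = skeleton,
       config = config)
}

#' Plant a known variance regime along the area axis
#'
#' Builds a single-solute site table whose concentration dispersion switches
#' at known area boundaries, for exercising the changepoint stage against
#' ground truth. Sites are taken from a skeleton, ordered by area; the
#' concentration is a constant offset plus normal noise whose sd is
#' `sds[k]` within regime `k`. The offset is `50 * max(sds)` so
#' concentrations stay positive.
#'
#' @param skeleton A [generate_network()] result.
#' @param boundaries_km2 Increasing area boundaries, strictly inside the
#'   skeleton's area range; a site belongs to regime `k` if its area exceeds
#'   `boundaries_km2[k - 1]` (and so on).
#' @param sds Regime standard deviations, `length(boundaries_km2) + 1`.
#' @param solute Which solute column to fill. Default `"DOC"`.
#' @param seed Optional seed for the noise draw.
#' @return List: `table` (site_table, one season), `truth` (boundaries,
#'   their ordered-position indices, regime sds).
#' @export
plant_variance_regime <- function(skeleton, boundaries_km2, sds,
                                  solute = "DOC", seed = NULL) {
  stopifnot(inherits(skeleton, "watershed_skeleton"))
  boundaries_km2 <- sort(boundaries_km2)
  if (length(sds) != length(boundaries_km2) + 1L) {
    stop("plant_variance_regime: need one sd per regime", call. = FALSE)
  }
  sites <- skeleton$sites
  rng <- range(sites$area_km2)
  if (any(boundaries_km2 <= rng[1]) || any(boundaries_km2 >= rng[2])) {
    stop("plant_variance_regime: boundary outside the skeleton's area range",
         call. = FALSE)
  }
  if (!is.null(seed)) withr::local_seed(seed)
  ord <- order(sites$area_km2, xtfrm(sites$site_id), method = "radix")
  sites <- sites[ord, ]
  regime <- findInterval(sites$area_km2, boundaries_km2) + 1L
  center <- 50 * max(sds)
  conc <- center + stats::rnorm(nrow(sites), 0, sds[regime])
  out <- sites[, c("site_id", "network", "category", "area_km2",
                   land_cover_classes(), "is_outlet")]
  out$season <- "Spring"
  out[[solute]] <- conc
  list(table = as_site_table(out, solutes = solute),
       truth = list(boundaries_km2 = boundaries_km2,
                    boundary_index = vapply(boundaries_km2, function(b)
                      sum(sites$area_km2 <= b), integer(1)),
                    sds = sds))
}
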