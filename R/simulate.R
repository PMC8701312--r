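#' Simulation configuration
#'
#' Defaults emulate the study conditions the pipeline targets: 33 + 37
#' subjects aged 11-18 scanned twice about 2.06 years apart, baseline
#' cortical thickness 2.7 mm with age-related thinning of about
#' -0.03 mm/year, between-subject baseline spread 0.1 mm and per-timepoint
#' measurement noise 0.05 mm, on an icosphere template whose two-hemisphere
#' scale area is of the order of the printed total surface area. Group
#' differences in thinning rate are planted as geodesic patches via
#' `planted_clusters`.
#'
#' @param seed master seed; every generator draws from a named sub-stream
#'   derived from it so one component's draws never perturb another's
#' @param n_asd,n_td group sizes
#' @param mesh_subdivisions icosphere subdivision level (4 gives 2562 vertices)
#' @param mesh_radius sphere radius, mm
#' @param baseline_ct baseline thickness, mm
#' @param thinning_rate_td neurotypical thinning rate, mm/year (negative)
#' @param group_rate_delta mm/year added to the ASD rate inside planted
#'   clusters (positive = reduced thinning)
#' @param planted_clusters list of `list(seed_vertex=, radius=, sign=)`
#'   patches (radius in geodesic mm along mesh edges)
#' @param subject_sd between-subject baseline spread, mm
#' @param noise_sd within-subject measurement noise per timepoint, mm
#' @param age_slope cross-sectional age effect on baseline thickness, mm/year
#' @param age_range years at T1, sampled uniformly
#' @param isi_mean,isi_sd interscan interval distribution, years
#' @param rbsr list: `missing_rate` (per-item MCAR missingness, capped at 3
#'   items per timepoint), optionally `size` (negative-binomial dispersion)
#' @param expression list: `n_genes`, `n_samples`, `n_planted`,
#'   `planted_correlation`
#' @return a `sim_config`
#' @export
sim_config <- function(seed = 1L, n_asd = 33L, n_td = 37L,
                       mesh_subdivisions = 4L, mesh_radius = 40,
                       baseline_ct = 2.7, thinning_rate_td = -0.03,
                       group_rate_delta = 0, planted_clusters = list(),
                       subject_sd = 0.1, noise_sd = 0.05,
                       age_slope = -0.03, age_range = c(11, 18),
                       isi_mean = 2.06, isi_sd = 0.24,
                       rbsr = list(), expression = list()) {
  cfg <- list(seed = as.integer(seed), n_asd = as.integer(n_asd),
              n_td = as.integer(n_td),
              mesh_subdivisions = as.integer(mesh_subdivisions),
              mesh_radius = mesh_radius, baseline_ct = baseline_ct,
              thinning_rate_td = thinning_rate_td,
              group_rate_delta = group_rate_delta,
              planted_clusters = planted_clusters,
              subject_sd = subject_sd, noise_sd = noise_sd,
              age_slope = age_slope, age_range = age_range,
              isi_mean = isi_mean, isi_sd = isi_sd,
              rbsr = utils::modifyList(list(missing_rate = 0.01, size = 0.6),
                                       rbsr),
              expression = utils::modifyList(
                list(n_genes = 1000L, n_samples = 200L, n_planted = 0L,
                     planted_correlation = 0.8), expression))
  if (cfg$subject_sd < 0 || cfg$noise_sd < 0 || cfg$isi_sd < 0) {
    stop("config error: standard deviations must be >= 0")
  }
  if (cfg$isi_mean <= 0) stop("config error: isi_mean must be > 0")
  for (pc in cfg$planted_clusters) {
    if (!all(c("seed_vertex", "radius") %in% names(pc))) {
      stop("config error: planted cluster needs seed_vertex and radius")
    }
    if (pc$radius > pi * cfg$mesh_radius) {
      stop("config error: planted cluster radius ", pc$radius,
           " mm exceeds the mesh diameter ", round(pi * cfg$mesh_radius, 1), " mm")
    }
  }
  structure(cfg, class = "sim_config")
}

# deterministic named sub-stream seeds derived from one master seed
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 1009 + h * 7919 + 12345) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
            rm(".Random.seed", envir = globalenv())
          })
  set.seed(seed)
  expr
}

# default four-factor item structure of the 43-item instrument:
# stereotyped 6 items, self-injurious 8, compulsive 8, persistent 21
# (ritualistic + sameness + restricted).
rbsr_subscale_items <- function() {
  list(F2_stereotyped = 1:6, F3_self_injurious = 7:14,
       F4_compulsive = 15:22, F1_persistent = 23:43)
}

# group-wise subscale means calibrated to the printed T1/T2 subscale
# summaries; per-item negative-binomial means are subscale mean / n items.
rbsr_group_means <- function() {
  list(
    ASD = list(t1 = c(F2_stereotyped = 3.06, F3_self_injurious = 0.88,
                      F4_compulsive = 4.36, F1_persistent = 16.88),
               t2 = c(F2_stereotyped = 2.70, F3_self_injurious = 1.06,
                      F4_compulsive = 3.76, F1_persistent = 14.97)),
    TD = list(t1 = c(F2_stereotyped = 0.30, F3_self_injurious = 0.05,
                     F4_compulsive = 0.16, F1_persistent = 1.59),
              t2 = c(F2_stereotyped = 0.08, F3_self_injurious = 0.03,
                     F4_compulsive = 0.38, F1_persistent = 1.81))
  )
}

#' Simulate a two-timepoint longitudinal cohort
#'
#' Generative model at vertex v for subject i:
#' latent thickness = baseline + subject offset + age_slope * (age_i - mean age);
#' observed CT(T1) = latent + noise; CT(T2) = latent + ISI_i * rate_i(v) + noise,
#' with rate_i(v) = thinning_rate_td + sign_c * group_rate_delta for ASD
#' subjects inside planted cluster c, thinning_rate_td elsewhere. Measurement
#' noise is independent per timepoint. Behavioral item responses are
#' truncated negative-binomial counts with group- and subscale-specific
#' means, a per-subject severity factor inducing within-person correlation
#' and overdispersion, and MCAR missingness capped at 3 items per timepoint.
#'
#' The planted truth (cluster label map, true rate delta) is returned in a
#' separate `truth` element that no analysis function reads.
#'
#' @param config a `sim_config`
#' @param mesh optional prebuilt `surface_mesh` (rebuilt from the config if
#'   omitted; passing one avoids recomputation across replicates)
#' @return a `synthetic_cohort`: list with `mesh`, `cohort` (observables),
#'   `ct_t1` / `ct_t2` (subjects x vertices, mm), and `truth`
#' @export
simulate_cohort <- function(config, mesh = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(mesh)) {
    mesh <- make_icosphere(config$mesh_subdivisions, config$mesh_radius)
  }
  nv <- n_vertices(mesh)
  n <- config$n_asd + config$n_td
  group <- factor(rep(c("ASD", "TD"), c(config$n_asd, config$n_td)),
                  levels = c("ASD", "TD"))

  demo <- with_seed(substream_seed(config$seed, "demographics"), {
    age <- stats::runif(n, config$age_range[1], config$age_range[2])
    isi <- pmax(0.5, stats::rnorm(n, config$isi_mean, config$isi_sd))
    fsiq <- ifelse(group == "ASD",
                   stats::rnorm(n, 101.38, 13.19),
                   stats::rnorm(n, 107.07, 11.52))
    sex <- factor(ifelse(stats::runif(n) < 0.815, "male", "female"),
                  levels = c("male", "female"))
    hand <- factor(ifelse(stats::runif(n) < 0.9, "right", "left"),
                   levels = c("right", "left"))
    list(age = age, isi = isi, fsiq = fsiq, sex = sex, hand = hand)
  })

  # planted effect geometry
  labels <- integer(nv)
  sign_map <- numeric(nv)
  if (length(config$planted_clusters)) {
    seeds <- vapply(config$planted_clusters, `[[`, 0, "seed_vertex")
    gd <- geodesic_distances(mesh, as.integer(seeds))
    for (k in seq_along(config$planted_clusters)) {
      pc <- config$planted_clusters[[k]]
      inside <- which(gd[k, ] <= pc$radius)
      labels[inside] <- k
      sign_map[inside] <- if (is.null(pc$sign)) 1 else pc$sign
    }
  }
  delta_map <- config$group_rate_delta * sign_map  # mm/year, ASD only

  thick <- with_seed(substream_seed(config$seed, "thickness"), {
    offset <- stats::rnorm(n, 0, config$subject_sd)
    latent0 <- config$baseline_ct + offset +
      config$age_slope * (demo$age - mean(demo$age))
    latent <- matrix(latent0, n, nv)
    rate <- matrix(config$thinning_rate_td, n, nv)
    if (any(delta_map != 0)) {
      rate <- rate + (group == "ASD") %o% delta_map
    }
    ct_t1 <- latent + matrix(stats::rnorm(n * nv, 0, config$noise_sd), n, nv)
    ct_t2 <- latent + demo$isi * rate +
      matrix(stats::rnorm(n * nv, 0, config$noise_sd), n, nv)
    list(ct_t1 = ct_t1, ct_t2 = ct_t2)
  })

  rb <- with_seed(substream_seed(config$seed, "behavior"),
                  simulate_rbsr_items(group, config$rbsr))

  subjects <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = group, sex = demo$sex, age_t1 = demo$age, isi = demo$isi,
    fsiq = demo$fsiq, handedness = demo$hand, stringsAsFactors = FALSE)
  cohort <- as_cohort(subjects, rbsr_t1 = rb$t1, rbsr_t2 = rb$t2)

  structure(list(
    mesh = mesh, cohort = cohort,
    ct_t1 = thick$ct_t1, ct_t2 = thick$ct_t2,
    truth = list(cluster_labels = labels,
                 group_rate_delta = config$group_rate_delta,
                 delta_map = delta_map,
                 config = config)
  ), class = "synthetic_cohort")
}

simulate_rbsr_items <- function(group, rbsr_cfg) {
  n <- length(group)
  items <- rbsr_subscale_items()
  means <- rbsr_group_means()
  size <- rbsr_cfg$size
  # per-subject severity factor: shared across timepoints, group-specific
  # dispersion reproducing the heavy ASD spread and zero-heavy TD totals;
  # the mean inflation compensates the 0-3 truncation of the item scale so
  # realized subscale means land on the configured targets
  sev <- ifelse(group == "ASD",
                stats::rgamma(n, shape = 1, rate = 1),
                stats::rgamma(n, shape = 0.45, rate = 0.45))
  inflate <- c(ASD = 1.45, TD = 1.1)
  draw_tp <- function(tp) {
    m <- matrix(0, n, 43L)
    for (f in names(items)) {
      idx <- items[[f]]
      for (g in c("ASD", "TD")) {
        rows <- which(group == g)
        mu_item <- inflate[[g]] * means[[g]][[tp]][[f]] / length(idx)
        lam <- sev[rows] %o% rep(mu_item, length(idx))
        x <- stats::rnbinom(length(lam), size = size, mu = as.vector(lam))
        m[rows, idx] <- pmin(matrix(x, length(rows)), 3L)
      }
    }
    m
  }
  t1 <- draw_tp("t1")
  t2 <- draw_tp("t2")
  punch <- function(m) {
    for (i in seq_len(nrow(m))) {
      miss <- which(stats::runif(43L) < rbsr_cfg$missing_rate)
      if (length(miss) > 3L) miss <- miss[1:3]
      m[i, miss] <- NA
    }
    m
  }
  list(t1 = punch(t1), t2 = punch(t2))
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", nrow(x$ct_t1), "subjects x",
      ncol(x$ct_t1), "vertices, two timepoints\n")
  print(x$cohort)
  k <- max(x$truth$cluster_labels)
  cat("  planted clusters:", k, "(truth channel; not read by analysis)\n")
  invisible(x)
}

#' Simulate a spatial gene-expression matrix
#'
#' Samples are placed at randomly chosen mesh vertices. `n_planted` genes
#' have expression `a * effect_map(sample vertex) + b + noise`, with the
#' signal fraction set so the expected correlation with the effect map at
#' the sample locations equals `planted_correlation`; the remaining genes
#' are spatially independent noise.
#'
#' @param mesh a `surface_mesh`
#' @param effect_map `vertex_map` or numeric vector (the map the planted
#'   genes track)
#' @param config list with `n_genes`, `n_samples`, `n_planted`,
#'   `planted_correlation`
#' @param seed integer seed
#' @return list: `expr` (genes x samples matrix), `samples` (data.frame
#'   sample_id, vertex), `planted` (character vector of planted gene ids)
#' @export
simulate_expression <- function(mesh, effect_map, config, seed = 1L) {
  ng <- config$n_genes
  ns <- config$n_samples
  np <- config$n_planted
  rho <- config$planted_correlation
  if (np > ng) stop("config error: n_planted > n_genes")
  if (ns < 3L) stop("config error: need at least 3 samples for correlation")
  vals <- map_values(effect_map)
  check_same_mesh(effect_map, mesh)
  with_seed(substream_seed(seed, "expression"), {
    vtx <- sample.int(n_vertices(mesh), ns, replace = FALSE)
    z <- vals[vtx]
    zs <- if (stats::sd(z) > 0) (z - mean(z)) / stats::sd(z) else z * 0
    expr <- matrix(stats::rnorm(ng * ns), ng, ns)
    genes <- sprintf("G%05d", seq_len(ng))
    rownames(expr) <- genes
    colnames(expr) <- sprintf("samp%04d", seq_len(ns))
    planted <- character(0)
    if (np > 0L) {
      planted <- genes[seq_len(np)]
      noise <- expr[seq_len(np), , drop = FALSE]
      expr[seq_len(np), ] <- rho * rep(1, np) %o% zs +
        sqrt(max(0, 1 - rho^2)) * noise
    }
    list(expr = expr,
         samples = data.frame(sample_id = colnames(expr), vertex = vtx),
         planted = planted)
  })
}
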