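#' Default cluster-by-program effect pattern
#'
#' Encodes the six-cluster score profile the generator plants: each row is a
#' cluster, each column one of the five gene programs, entries are the
#' symbolic shifts applied to that program's genes in that cluster
#' (`-dh`, `-dl`, `0`, `+dl`, `+dh` for minus/plus delta-high/delta-low).
#' Cluster 1 is the IC-low/IL1B-low extreme and cluster 6 the
#' IC-high/IL18-high extreme; for directional programs the shift applies to
#' the up-regulated set and is mirrored (sign-flipped) on the down-regulated
#' set, so the composite score moves twice as far as a single set.
#'
#' @return A 6 x 5 character matrix (clusters x `IC, CASP1, GSDMD, IL1B, IL18`).
#' @export
default_pattern_table <- function() {
  pat <- rbind(
    c("-dh", "-dl", "-dl", "-dh", "-dl"),  # 1: IC^Low  IL1B^Low
    c("-dh", "-dl", "0",   "+dh", "0"),    # 2: IC^Low  IL1B^High
    c("0",   "+dh", "0",   "0",   "-dl"),  # 3: IC^Mid  CASP1^High
    c("0",   "-dl", "+dl", "0",   "+dh"),  # 4: IC^Mid  IL18^High
    c("+dh", "+dl", "0",   "+dl", "-dh"),  # 5: IC^High IL18^Low
    c("+dh", "+dl", "+dl", "+dl", "+dh")   # 6: IC^High IL18^High
  )
  dimnames(pat) <- list(cluster = 1:6, program = SCORE_NAMES)
  pat
}

#' Configuration of the synthetic cohort generator
#'
#' The generator emulates a log2-scale gene-by-sample expression matrix in
#' which the five inflammasome gene programs are shifted per planted cluster
#' according to [default_pattern_table()], with Gaussian residual noise,
#' tumor-type labels drawn from cluster-specific multinomials (uneven, so
#' type enrichment is non-trivial) and cluster-dependent exponential
#' survival with uniform censoring.
#'
#' @param scheme A [signature_scheme()]; its genes are embedded in the
#'   simulated universe.
#' @param n_genes Total genes including background (default 2000).
#' @param samples_per_cluster Integer vector of 6 cluster sizes
#'   (default 100 each).
#' @param delta_high,delta_low Strong/weak program shifts in log2 units
#'   (defaults 1.5 / 0.6).
#' @param noise_sd Residual Gaussian standard deviation (default 1.0).
#' @param pattern 6 x 5 character pattern matrix (see
#'   [default_pattern_table()]).
#' @param tumor_type_profile 6 x types probability matrix; default: eight
#'   synthetic types `T1..T8` with each cluster k placing weight 0.45 on
#'   type `Tk` and spreading the rest evenly (types `T7`, `T8` are
#'   background-only).
#' @param hazard_multipliers Per-cluster hazard scale (default
#'   `c(1, 1.2, 0.8, 1.1, 1.4, 2.2)`; cluster 6 largest, i.e. worst
#'   prognosis).
#' @param base_hazard Baseline exponential hazard (default 0.05 per time
#'   unit).
#' @param censoring_rate Target fraction of censored samples (default 0.3),
#'   realized through independent uniform censoring times.
#' @param seed RNG seed.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(scheme = default_scheme(),
                             n_genes = 2000,
                             samples_per_cluster = rep(100L, 6),
                             delta_high = 1.5, delta_low = 0.6,
                             noise_sd = 1.0,
                             pattern = default_pattern_table(),
                             tumor_type_profile = NULL,
                             hazard_multipliers = c(1, 1.2, 0.8, 1.1, 1.4, 2.2),
                             base_hazard = 0.05,
                             censoring_rate = 0.3,
                             seed = 1) {
  stopifnot(inherits(scheme, "signature_scheme"))
  if (length(samples_per_cluster) != 6L || any(samples_per_cluster <= 0)) {
    fail("samples_per_cluster must be 6 positive counts")
  }
  if (any(hazard_multipliers <= 0)) fail("hazard multipliers must be positive")
  if (!all(dim(pattern) == c(6, 5)) ||
      !all(pattern %in% c("-dh", "-dl", "0", "+dl", "+dh"))) {
    fail("pattern must be 6 x 5 over {-dh, -dl, 0, +dl, +dh}")
  }
  genes <- scheme_genes(scheme)
  if (length(genes) > n_genes) {
    fail("scheme has %d genes but n_genes = %d", length(genes), n_genes)
  }
  if (is.null(tumor_type_profile)) {
    tumor_type_profile <- matrix(0.55 / 7, 6, 8,
                                 dimnames = list(1:6, paste0("T", 1:8)))
    for (k in 1:6) tumor_type_profile[k, k] <- 0.45
  }
  if (nrow(tumor_type_profile) != 6L ||
      any(abs(rowSums(tumor_type_profile) - 1) > 1e-8)) {
    fail("tumor_type_profile must be 6 rows of probabilities summing to 1")
  }
  structure(list(scheme = scheme, n_genes = as.integer(n_genes),
                 samples_per_cluster = as.integer(samples_per_cluster),
                 delta_high = delta_high, delta_low = delta_low,
                 noise_sd = noise_sd, pattern = pattern,
                 tumor_type_profile = tumor_type_profile,
                 hazard_multipliers = hazard_multipliers,
                 base_hazard = base_hazard,
                 censoring_rate = censoring_rate, seed = as.integer(seed)),
            class = "synthetic_config")
}

# numeric shift for a symbolic pattern entry
.pattern_value <- function(sym, dh, dl) {
  switch(sym, "-dh" = -dh, "-dl" = -dl, "0" = 0, "+dl" = dl, "+dh" = dh)
}

# per-gene signed program membership: list of (program, sign) for each gene
.gene_programs <- function(scheme) {
  out <- list()
  for (nm in names(scheme$scores)) {
    sc <- scheme$scores[[nm]]
    for (g in sc$positive$members) {
      out[[g]] <- rbind(out[[g]], c(program = nm, sign = 1))
    }
    if (!is.null(sc$negative)) {
      for (g in sc$negative$members) {
        out[[g]] <- rbind(out[[g]], c(program = nm, sign = -1))
      }
    }
  }
  out
}

#' Generate a synthetic cohort with planted inflammasome clusters
#'
#' Gene g in sample s is drawn as
#' `Normal(mu_g + Delta(cluster(s), program(g)), noise_sd)` with baseline
#' `mu_g ~ Normal(5, 1)` on the log2 scale; genes in a down-regulated set
#' receive the sign-flipped program shift, and background genes no shift.
#' Tumor types follow the per-cluster multinomial profile. Survival times
#' are exponential with rate `base_hazard * multiplier(cluster)`; censoring
#' times are uniform on `(0, c_max)` with `c_max` solved so the expected
#' censored fraction matches `censoring_rate` under the cohort's average
#' hazard. The cohort is bitwise reproducible from its echoed config.
#'
#' @param config A [synthetic_config()].
#' @return An object of class `synthetic_cohort`: list with `expr` (an
#'   [expression_matrix()] with metadata columns `tumor_type`, `time`,
#'   `event`), `true_labels`, `tumor_types`, `survival` (data.frame), and
#'   `config`.
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  scheme_g <- scheme_genes(config$scheme)
  n_bg <- config$n_genes - length(scheme_g)
  genes <- c(scheme_g, if (n_bg > 0) sprintf("BG%04d", seq_len(n_bg)))
  n <- sum(config$samples_per_cluster)
  cluster <- rep(1:6, times = config$samples_per_cluster)
  samples <- sprintf("SAMP%04d", seq_len(n))

  # per-cluster, per-gene mean shift
  programs <- .gene_programs(config$scheme)
  delta <- matrix(0, length(genes), 6, dimnames = list(genes, 1:6))
  for (g in names(programs)) {
    memb <- programs[[g]]
    for (r in seq_len(nrow(memb))) {
      prog <- memb[r, "program"]; sgn <- as.numeric(memb[r, "sign"])
      for (k in 1:6) {
        delta[g, k] <- delta[g, k] + sgn *
          .pattern_value(config$pattern[k, prog], config$delta_high,
                         config$delta_low)
      }
    }
  }

  mu <- stats::rnorm(length(genes), mean = 5, sd = 1)
  expr <- matrix(stats::rnorm(length(genes) * n, sd = config$noise_sd),
                 length(genes), n, dimnames = list(genes, samples))
  expr <- expr + mu + delta[, cluster]

  types <- colnames(config$tumor_type_profile)
  tumor_types <- vapply(cluster, function(k) {
    sample(types, 1L, prob = config$tumor_type_profile[k, ])
  }, character(1))

  rate <- config$base_hazard * config$hazard_multipliers[cluster]
  t_event <- stats::rexp(n, rate = rate)
  mean_rate <- mean(config$base_hazard * config$hazard_multipliers)
  cmax <- .censoring_cmax(mean_rate, config$censoring_rate)
  t_cens <- stats::runif(n, 0, cmax)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  # exponential times are continuous and positive almost surely, but guard
  time[time <= 0] <- .Machine$double.eps

  metadata <- data.frame(tumor_type = tumor_types, time = time,
                         event = event, true_cluster = cluster,
                         row.names = samples, stringsAsFactors = FALSE)
  structure(list(
    expr = expression_matrix(expr, metadata = metadata),
    true_labels = stats::setNames(cluster, samples),
    tumor_types = stats::setNames(tumor_types, samples),
    survival = data.frame(sample = samples, time = time, event = event,
                          stringsAsFactors = FALSE),
    config = config), class = "synthetic_cohort")
}

# solve the uniform-censoring horizon so that, for T ~ Exp(rate) and
# C ~ U(0, cmax), P(C < T) = target; P(C < T) = (1 - exp(-rate*u)) / (rate*u)
.censoring_cmax <- function(rate, target) {
  if (target <= 0) return(Inf)
  f <- function(u) (1 - exp(-rate * u)) / (rate * u) - target
  stats::uniroot(f, lower = 1e-8 / rate, upper = 1e6 / rate)$root
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d genes x %d samples, 6 planted clusters\n",
              nrow(x$expr$values), ncol(x$expr$values)))
  print(table(planted = x$true_labels))
  invisible(x)
}

#' Generate paired case/control profiles for curation round-trips
#'
#' Produces datasets mimicking perturbation experiments used to curate
#' regulated gene sets: in each dataset the target node's up-set genes are
#' shifted up and its down-set genes down by `shift` log2 units in the case
#' arm, on top of Gaussian noise, so that [screen_degs()] followed by
#' [intersect_regulated()] recovers the planted sets.
#'
#' @param config A [synthetic_config()] (supplies the scheme, gene universe
#'   and seed).
#' @param target One of `"CASP1"`, `"GSDMD"`, `"IL1B"`, `"IL18"`.
#' @param n_datasets Number of independent case/control pairs (default 3).
#' @param n_replicates Replicates per arm (default 3; 1 gives the
#'   logFC-only single-profile mode).
#' @param shift Planted absolute shift in log2 units (default 2).
#' @param noise_sd Noise standard deviation (default 0.5).
#' @return List of length `n_datasets`; each element has `case` and
#'   `control` gene x replicate matrices.
#' @export
generate_regulated_profiles <- function(config = synthetic_config(),
                                        target = c("CASP1", "GSDMD", "IL1B",
                                                   "IL18"),
                                        n_datasets = 3, n_replicates = 3,
                                        shift = 2, noise_sd = 0.5) {
  target <- match.arg(target)
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  sc <- config$scheme$scores[[target]]
  up <- sc$positive$members
  dn <- if (is.null(sc$negative)) character(0) else sc$negative$members
  scheme_g <- scheme_genes(config$scheme)
  n_bg <- max(0L, config$n_genes - length(scheme_g))
  genes <- c(scheme_g, if (n_bg > 0) sprintf("BG%04d", seq_len(n_bg)))
  mu <- stats::rnorm(length(genes), 5, 1)
  lapply(seq_len(n_datasets), function(d) {
    mk <- function(shifted) {
      m <- matrix(stats::rnorm(length(genes) * n_replicates, sd = noise_sd),
                  length(genes), n_replicates,
                  dimnames = list(genes, paste0("rep", seq_len(n_replicates))))
      m <- m + mu
      if (shifted) {
        m[up, ] <- m[up, ] + shift
        if (length(dn) > 0) m[dn, ] <- m[dn, ] - shift
      }
      m
    }
    list(case = mk(TRUE), control = mk(FALSE))
  })
}

#' Per-cluster Bernoulli binary feature generator
#'
#' Simple companion generator for exercising the binary-feature screen: each
#' feature has a background presence rate, optionally elevated in one
#' cluster.
#'
#' @param labels Cluster assignment per sample.
#' @param n_features Number of features.
#' @param background_rate Presence probability outside the enriched cluster.
#' @param enriched Named numeric vector mapping `feature index -> cluster`
#'   whose rate is raised to `enriched_rate`.
#' @param enriched_rate Presence probability inside the enriched cluster.
#' @param seed RNG seed.
#' @return Samples x features 0/1 matrix.
#' @export
generate_binary_features <- function(labels, n_features = 20,
                                     background_rate = 0.1,
                                     enriched = c(`1` = 1), enriched_rate = 0.6,
                                     seed = 1) {
  set.seed(seed)
  n <- length(labels)
  m <- matrix(stats::rbinom(n * n_features, 1, background_rate), n, n_features,
              dimnames = list(names(labels), sprintf("FEAT%02d", seq_len(n_features))))
  for (f in names(enriched)) {
    idx <- labels == enriched[[f]]
    m[idx, as.integer(f)] <- stats::rbinom(sum(idx), 1, enriched_rate)
  }
  m
}

#' Write a synthetic cohort as the standard TSV trio
#'
#' Writes `expression.tsv` (genes x samples), `metadata.tsv` (sample,
#' tumor_type, true_cluster) and `survival.tsv` (sample, time, event) into
#' `dir`, with deterministic ordering.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(cohort$expr, file.path(dir, "expression.tsv"))
  md <- data.frame(sample = names(cohort$true_labels),
                   tumor_type = unname(cohort$tumor_types),
                   true_cluster = unname(cohort$true_labels),
                   stringsAsFactors = FALSE)
  write_tsv_plain(md[order(md$sample), ], file.path(dir, "metadata.tsv"))
  sv <- cohort$survival[order(cohort$survival$sample), ]
  write_tsv_plain(sv, file.path(dir, "survival.tsv"))
  invisible(dir)
}
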