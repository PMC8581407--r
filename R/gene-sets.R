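#' Directional inflammasome-signaling gene set
#'
#' A gene set annotated with the inflammasome signaling step it belongs to
#' (sensing, activation or termination) and a direction. The sensing set
#' (the inflammasome-complex, "IC", genes) is the only `core` set: its
#' enrichment is used directly. Every other signaling node (CASP1, GSDMD,
#' IL1B, IL18) undergoes post-translational control, so its activity is read
#' out through genes it regulates, split into an up-regulated and a
#' down-regulated set.
#'
#' @param name Set identifier (e.g. `"IL18_UP"`).
#' @param step One of `"sensing"`, `"activation"`, `"termination"`.
#' @param members Character vector of gene symbols; non-empty, no duplicates.
#' @param direction One of `"core"`, `"up_regulated"`, `"down_regulated"`.
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(name, step, members, direction) {
  step <- match.arg(step, c("sensing", "activation", "termination"))
  direction <- match.arg(direction, c("core", "up_regulated", "down_regulated"))
  members <- as.character(members)
  if (length(members) == 0L) fail("gene set '%s' is empty", name)
  if (anyDuplicated(members)) {
    fail("gene set '%s' contains duplicate symbols: %s", name,
         paste(unique(members[duplicated(members)]), collapse = ", "))
  }
  if (direction == "core" && step != "sensing") {
    fail("direction 'core' is reserved for the sensing (IC) set; set '%s' has step '%s'",
         name, step)
  }
  structure(list(name = name, step = step, members = members,
                 direction = direction),
            class = "gene_set")
}

SCORE_NAMES <- c("IC", "CASP1", "GSDMD", "IL1B", "IL18")

#' Five-score inflammasome signature scheme
#'
#' Bundles the five score definitions: `IC` is the plain enrichment of the
#' core sensing set; `CASP1`, `GSDMD`, `IL1B` and `IL18` are each defined as
#' the enrichment of a positive (up-regulated) set minus the enrichment of a
#' negative (down-regulated) set.
#'
#' @param scores Named list over exactly `IC, CASP1, GSDMD, IL1B, IL18`; each
#'   element a list with `positive` (a [gene_set()]) and optionally
#'   `negative` (a [gene_set()] or `NULL`).
#' @return An object of class `signature_scheme`.
#' @export
signature_scheme <- function(scores) {
  missing <- setdiff(SCORE_NAMES, names(scores))
  if (length(missing) > 0L) {
    fail("incomplete scheme: missing score(s) %s", paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(scores), SCORE_NAMES)
  if (length(extra) > 0L) {
    fail("unknown score name(s): %s", paste(extra, collapse = ", "))
  }
  scores <- scores[SCORE_NAMES]
  for (nm in SCORE_NAMES) {
    sc <- scores[[nm]]
    if (is.null(sc$positive) || !inherits(sc$positive, "gene_set")) {
      fail("score '%s' lacks a positive gene set", nm)
    }
    if (!is.null(sc$negative) && !inherits(sc$negative, "gene_set")) {
      fail("score '%s': negative component is not a gene_set", nm)
    }
  }
  if (!is.null(scores$IC$negative)) {
    fail("the IC score is a plain enrichment and takes no negative set")
  }
  structure(list(scores = scores), class = "signature_scheme")
}

#' @export
print.signature_scheme <- function(x, ...) {
  cat("signature_scheme with", length(x$scores), "scores\n")
  for (nm in names(x$scores)) {
    sc <- x$scores[[nm]]
    neg <- if (is.null(sc$negative)) "" else
      sprintf(" - %s (%d genes)", sc$negative$name, length(sc$negative$members))
    cat(sprintf("  %-5s = %s (%d genes)%s\n", nm, sc$positive$name,
                length(sc$positive$members), neg))
  }
  cat("unique genes:", length(scheme_genes(x)), "\n")
  invisible(x)
}

#' All unique genes of a scheme
#'
#' @param scheme A `signature_scheme`.
#' @return Sorted character vector of the union of all member symbols.
#' @export
scheme_genes <- function(scheme) {
  stopifnot(inherits(scheme, "signature_scheme"))
  sets <- scheme_sets(scheme)
  sort(unique(unlist(lapply(sets, `[[`, "members"), use.names = FALSE)))
}

# flat list of all gene_set objects in a scheme, names = set names
scheme_sets <- function(scheme) {
  out <- list()
  for (sc in scheme$scores) {
    out[[sc$positive$name]] <- sc$positive
    if (!is.null(sc$negative)) out[[sc$negative$name]] <- sc$negative
  }
  out
}

#' Load a signature scheme from GMT plus a direction sidecar
#'
#' GMT carries no direction or step information, so each set is annotated via
#' a tab-separated sidecar with columns `set_name`, `score_name`, `step`,
#' `direction`. Sets whose GMT name ends in `_UP` / `_DN` may omit a sidecar
#' row only if the sidecar still maps them to a score; every set present in
#' the GMT must have a sidecar annotation.
#'
#' @param gmt_path Path to a GMT file (one set per line: name, description,
#'   then member symbols).
#' @param sidecar_path Path to the direction sidecar TSV.
#' @param quiet Suppress the loaded-scheme summary message.
#' @return A validated [signature_scheme()].
#' @export
load_scheme <- function(gmt_path, sidecar_path, quiet = FALSE) {
  sets_raw <- fgsea::gmtPathways(gmt_path)
  if (length(sets_raw) == 0L) fail("no gene sets found in '%s'", gmt_path)
  side <- read_tsv_plain(sidecar_path)
  need <- c("set_name", "score_name", "step", "direction")
  if (!all(need %in% names(side))) {
    fail("direction sidecar must have columns: %s", paste(need, collapse = ", "))
  }
  unannotated <- setdiff(names(sets_raw), side$set_name)
  if (length(unannotated) > 0L) {
    fail("missing direction annotation for set(s): %s",
         paste(unannotated, collapse = ", "))
  }
  scores <- stats::setNames(vector("list", length(SCORE_NAMES)), SCORE_NAMES)
  for (nm in names(sets_raw)) {
    row <- side[side$set_name == nm, , drop = FALSE][1L, ]
    gs <- gene_set(nm, row$step, sets_raw[[nm]], row$direction)
    slot <- if (gs$direction == "down_regulated") "negative" else "positive"
    if (!row$score_name %in% SCORE_NAMES) {
      fail("sidecar maps set '%s' to unknown score '%s'", nm, row$score_name)
    }
    scores[[row$score_name]][[slot]] <- gs
  }
  scheme <- signature_scheme(scores[!vapply(scores, is.null, logical(1))])
  if (!quiet) {
    message(sprintf("loaded scheme: %d sets, %d unique genes",
                    length(scheme_sets(scheme)), length(scheme_genes(scheme))))
  }
  scheme
}

#' The packaged inflammasome signature scheme
#'
#' Loads the five directional gene sets shipped with the package. The shipped
#' compendium is a synthetic stand-in with the canonical set structure (a
#' 15-gene inflammasome-complex sensing set; CASP1-regulated,
#' GSDMD-regulated, IL1B-regulated and IL18-regulated sets of 34, 13, 72 and
#' 8 genes, split into up/down components; 141 unique genes in total): the IC
#' members are canonical inflammasome-complex genes, the regulated sets mix
#' real inflammation-response symbols with placeholder symbols. See the
#' package vignette for why original curated lists are not
#' redistributed.
#'
#' @param quiet Suppress the loading message.
#' @return A [signature_scheme()].
#' @export
default_scheme <- function(quiet = TRUE) {
  gmt <- system.file("extdata", "inflammasome_sets_synthetic.gmt",
                     package = "inflaclust", mustWork = TRUE)
  side <- system.file("extdata", "inflammasome_sets_synthetic_directions.tsv",
                      package = "inflaclust", mustWork = TRUE)
  load_scheme(gmt, side, quiet = quiet)
}

#' Screen differentially expressed genes between two expression profiles
#'
#' Computes per-gene log fold change (mean difference on the log scale) and,
#' when both arms carry at least two replicates, a Welch t-test p-value.
#' Genes passing `|logFC| > logfc_min` and `p < p_max` are returned sorted by
#' decreasing `|logFC|`. With a single replicate per arm no p-value can be
#' formed: records carry `p = NA` and only the fold-change filter applies.
#'
#' @param case_profile,control_profile Numeric matrices (genes x replicates,
#'   rownames = symbols) or named vectors (single replicate).
#' @param logfc_min Absolute log2 fold-change threshold (default 1).
#' @param p_max P-value threshold (default 0.05).
#' @return A data.frame with columns `gene`, `logFC`, `p`, `direction`
#'   (`"up"`/`"down"`), sorted by decreasing `|logFC|`.
#' @export
screen_degs <- function(case_profile, control_profile,
                        logfc_min = 1, p_max = 0.05) {
  as_mat <- function(x) {
    if (is.null(dim(x))) x <- matrix(x, ncol = 1, dimnames = list(names(x), NULL))
    if (is.null(rownames(x))) fail("profiles must carry gene symbols as names")
    x
  }
  case <- as_mat(case_profile)
  ctrl <- as_mat(control_profile)
  shared <- intersect(rownames(case), rownames(ctrl))
  if (length(shared) == 0L) fail("case and control profiles share no genes")
  case <- case[shared, , drop = FALSE]
  ctrl <- ctrl[shared, , drop = FALSE]
  logfc <- rowMeans(case) - rowMeans(ctrl)
  if (ncol(case) >= 2L && ncol(ctrl) >= 2L) {
    p <- vapply(seq_along(shared), function(i) {
      stats::t.test(case[i, ], ctrl[i, ])$p.value
    }, numeric(1))
    keep <- abs(logfc) > logfc_min & p < p_max
  } else {
    p <- rep(NA_real_, length(shared))
    keep <- abs(logfc) > logfc_min
  }
  out <- data.frame(gene = shared, logFC = unname(logfc), p = unname(p),
                    direction = ifelse(logfc > 0, "up", "down"),
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  out <- out[order(-abs(out$logFC)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Consistent-direction meta-analysis vote over DEG lists
#'
#' A gene is retained if it appears with the same direction in at least
#' `min_support` of the supplied DEG lists; genes reported up in one list and
#' down in another are dropped. With `min_support` equal to the number of
#' lists this is the strict direction-consistent intersection.
#'
#' @param deg_lists List of data.frames as returned by [screen_degs()].
#' @param min_support Minimum number of supporting lists (default: all).
#' @return List with `up_regulated` and `down_regulated` character vectors
#'   (sorted).
#' @export
intersect_regulated <- function(deg_lists, min_support = length(deg_lists)) {
  if (length(deg_lists) == 0L) fail("no DEG lists supplied")
  if (min_support > length(deg_lists)) {
    fail("min_support (%d) exceeds number of lists (%d)",
         min_support, length(deg_lists))
  }
  votes <- do.call(rbind, lapply(deg_lists, function(d) {
    unique(d[, c("gene", "direction"), drop = FALSE])
  }))
  up_n <- table(votes$gene[votes$direction == "up"])
  dn_n <- table(votes$gene[votes$direction == "down"])
  conflicted <- intersect(names(up_n), names(dn_n))
  list(
    up_regulated = sort(setdiff(names(up_n)[up_n >= min_support], conflicted)),
    down_regulated = sort(setdiff(names(dn_n)[dn_n >= min_support], conflicted))
  )
}
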