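#' Repertoire clone tables
#'
#' A repertoire is a tibble with one row per unique TCR-beta rearrangement and
#' columns `cdr3_nt` (nucleotide CDR3, the clone identity key), `cdr3_aa`
#' (amino-acid CDR3), `count` (template count, non-negative integer),
#' `frequency` (proportion of total templates) and `productive` (logical).
#' Sample metadata (sample id, compartment, subset, timepoint) travels in
#' ordinary columns or in the file name; the metrics below only require the
#' clone columns. Frequencies are always recomputed from counts after any
#' filtering; stored frequencies are never trusted.
#'
#' @param clones A data frame with at least `cdr3_nt` and `count`; `cdr3_aa`
#'   and `productive` are filled with defaults when absent.
#' @return A tibble with the canonical clone columns, frequencies recomputed.
#' @export
#' @examples
#' as_repertoire(data.frame(cdr3_nt = c("TGTGCC", "TGTGCG"), count = c(8, 2)))
as_repertoire <- function(clones) {
  stopifnot(is.data.frame(clones))
  if (!all(c("cdr3_nt", "count") %in% names(clones))) {
    abort("a repertoire needs at least `cdr3_nt` and `count` columns",
          class = "tilmonitor_bad_repertoire")
  }
  out <- tibble::as_tibble(clones)
  if (!"cdr3_aa" %in% names(out)) out$cdr3_aa <- NA_character_
  if (!"productive" %in% names(out)) out$productive <- TRUE
  if (any(out$count < 0)) {
    abort("clone counts must be non-negative", class = "tilmonitor_bad_repertoire")
  }
  if (anyDuplicated(out$cdr3_nt)) {
    # collapse duplicate rearrangements (e.g. after aa-level grouping upstream)
    out <- out |>
      dplyr::group_by(cdr3_nt) |>
      dplyr::summarise(
        cdr3_aa = dplyr::first(cdr3_aa),
        count = sum(count),
        productive = any(productive),
        .groups = "drop"
      )
  }
  out <- dplyr::filter(out, count > 0)
  recompute_frequency(out)
}

recompute_frequency <- function(rep) {
  total <- sum(rep$count)
  rep$frequency <- if (total > 0) rep$count / total else rep(NA_real_, nrow(rep))
  rep
}

stop_if_empty_repertoire <- function(rep, context) {
  if (nrow(rep) == 0 || sum(rep$count) == 0) {
    abort(paste0("empty repertoire in ", context,
                 " (no clones with positive counts remain)"),
          class = "tilmonitor_empty_repertoire")
  }
  invisible(rep)
}

#' Keep only productive rearrangements
#'
#' Out-of-frame and stop-codon-containing rearrangements carry no receptor and
#' are excluded before any diversity or overlap statistic; remaining clone
#' frequencies are renormalized to sum to 1.
#'
#' @param rep A repertoire tibble (see [as_repertoire()]).
#' @return The productive subset with frequencies renormalized.
#' @export
filter_productive <- function(rep) {
  rep <- as_repertoire(rep)
  out <- dplyr::filter(rep, productive)
  stop_if_empty_repertoire(out, "filter_productive")
  recompute_frequency(out)
}

#' Clonality of a repertoire
#'
#' Clonality is one minus the Pielou-normalized Shannon entropy of clone
#' frequencies: `C = 1 - H / ln(R)` with `H = -sum(p_i * ln p_i)` over the `R`
#' unique nucleotide rearrangements. 1 indicates a monoclonal population;
#' values near 0 a diverse, polyclonal one. A single-clone repertoire is
#' defined as clonality 1 (the monoclonal limit of the 0/0 case).
#'
#' @param rep A repertoire tibble; non-productive clones are dropped first.
#' @param productive_only Filter to productive rearrangements first (default
#'   TRUE).
#' @return A number in \[0, 1\].
#' @export
#' @examples
#' clonality(as_repertoire(data.frame(cdr3_nt = c("a", "b"), count = c(8, 2))))
clonality <- function(rep, productive_only = TRUE) {
  rep <- if (productive_only) filter_productive(rep) else as_repertoire(rep)
  stop_if_empty_repertoire(rep, "clonality")
  p <- rep$count / sum(rep$count)
  r <- length(p)
  if (r == 1) return(1)
  h <- -sum(p * log(p))
  unname(1 - h / log(r))
}

#' Morisita-Horn overlap between two repertoires
#'
#' Abundance-weighted overlap of two clone-count distributions:
#' `MH = 2 * sum(x_i * y_i) / ((d_x + d_y) * X * Y)` where `X = sum(x_i)`,
#' `Y = sum(y_i)`, `d_x = sum(x_i^2)/X^2`, `d_y = sum(y_i^2)/Y^2`, and the sum
#' in the numerator runs over clones shared by both repertoires. 0 for
#' disjoint clone sets, 1 for identical count distributions. Symmetric and
#' invariant to uniform scaling of either repertoire's counts.
#'
#' @param a,b Repertoire tibbles.
#' @param by Clone identity key: `"cdr3_nt"` (default; nucleotide-level
#'   comparison) or `"cdr3_aa"` for convergence-style amino-acid grouping.
#' @param top_n Optionally restrict both repertoires to their top `top_n`
#'   clones by count before comparison (default NULL: all clones).
#' @param productive_only Filter to productive rearrangements first.
#' @return A number in \[0, 1\] (clamped within 1e-12 of the bounds).
#' @export
#' @examples
#' a <- as_repertoire(data.frame(cdr3_nt = c("A", "B"), count = c(3, 1)))
#' b <- as_repertoire(data.frame(cdr3_nt = c("A", "B"), count = c(1, 3)))
#' morisita_horn(a, b) # 0.6
morisita_horn <- function(a, b, by = c("cdr3_nt", "cdr3_aa"), top_n = NULL,
                          productive_only = TRUE) {
  by <- match.arg(by)
  prep <- function(rep, label) {
    rep <- if (productive_only) filter_productive(rep) else as_repertoire(rep)
    stop_if_empty_repertoire(rep, paste0("morisita_horn (", label, ")"))
    counts <- tapply(rep$count, rep[[by]], sum)
    counts <- tibble::tibble(key = names(counts), count = as.numeric(counts))
    if (!is.null(top_n)) {
      counts <- counts |>
        dplyr::arrange(dplyr::desc(count), key) |>
        dplyr::slice_head(n = top_n)
    }
    counts
  }
  xa <- prep(a, "a")
  xb <- prep(b, "b")
  m <- dplyr::full_join(xa, xb, by = "key", suffix = c("_a", "_b")) |>
    dplyr::mutate(dplyr::across(dplyr::starts_with("count"), ~ tidyr::replace_na(.x, 0)))
  x <- m$count_a
  y <- m$count_b
  bigx <- sum(x)
  bigy <- sum(y)
  dx <- sum(x^2) / bigx^2
  dy <- sum(y^2) / bigy^2
  mh <- 2 * sum(x * y) / ((dx + dy) * bigx * bigy)
  # clamp tiny numerical excursions outside [0, 1]
  if (mh > 1 && mh <= 1 + 1e-12) mh <- 1
  if (mh < 0 && mh >= -1e-12) mh <- 0
  mh
}

#' Top-N clones and their cumulative frequency
#'
#' Clones sorted by template count descending, ties broken by nucleotide CDR3
#' lexicographically (deterministic across platforms). When `n` exceeds the
#' richness all clones are returned.
#'
#' @param rep A repertoire tibble.
#' @param n Number of clones to keep (>= 1).
#' @param productive_only Filter to productive rearrangements first.
#' @return The top-`n` clone tibble with an attribute `cumulative_frequency`,
#'   also exposed via [cumulative_frequency()].
#' @export
top_n_clones <- function(rep, n = 30, productive_only = TRUE) {
  stopifnot(n >= 1)
  rep <- if (productive_only) filter_productive(rep) else as_repertoire(rep)
  stop_if_empty_repertoire(rep, "top_n_clones")
  out <- rep |>
    dplyr::arrange(dplyr::desc(count), cdr3_nt) |>
    dplyr::slice_head(n = n)
  attr(out, "cumulative_frequency") <- sum(out$frequency)
  out
}

#' @rdname top_n_clones
#' @param top A tibble returned by [top_n_clones()].
#' @export
cumulative_frequency <- function(top) {
  cf <- attr(top, "cumulative_frequency")
  cf %||% sum(top$frequency)
}

#' Track top clones of a reference repertoire across other samples
#'
#' For each of the top-`n` clones of `reference` (by count, deterministic
#' tie-break), reports its frequency in every comparator repertoire (0 when
#' absent) and per-comparator shared-clone counts — e.g. how many of the top 30
#' day-of-surgery DP TIL clones were already present in the pre-treatment
#' biopsy or in peripheral blood.
#'
#' @param reference Repertoire whose top clones are tracked.
#' @param others Named list of comparator repertoires.
#' @param n Number of reference clones to track (default 30).
#' @param by Clone identity key.
#' @return A list with `trajectory` (one row per clone x comparator, columns
#'   `cdr3_nt`, `reference_frequency`, `comparator`, `frequency`, `present`)
#'   and `shared` (one row per comparator with its shared-clone count).
#' @export
track_clones <- function(reference, others, n = 30, by = c("cdr3_nt", "cdr3_aa")) {
  by <- match.arg(by)
  stopifnot(n >= 1, is.list(others), length(others) >= 1)
  if (is.null(names(others)) || any(!nzchar(names(others)))) {
    names(others) <- paste0("comparator_", seq_along(others))
  }
  top <- top_n_clones(reference, n)
  traj <- purrr::imap_dfr(others, function(rep, label) {
    rep <- filter_productive(rep)
    freq <- tapply(rep$frequency, rep[[by]], sum)
    f <- as.numeric(freq[match(top[[by]], names(freq))])
    f[is.na(f)] <- 0
    tibble::tibble(
      !!by := top[[by]],
      reference_frequency = top$frequency,
      comparator = label,
      frequency = f,
      present = f > 0
    )
  })
  shared <- traj |>
    dplyr::group_by(comparator) |>
    dplyr::summarise(shared_clones = sum(present), .groups = "drop")
  list(trajectory = traj, shared = shared)
}

#' Call dominant (reactive) clones above a frequency cutoff
#'
#' Returns clones whose frequency strictly exceeds `cutoff`, sorted by
#' frequency descending — the rule used to call antigen-reactive dominant
#' clones in sorted reactive fractions (e.g. a 2% cutoff).
#'
#' @param rep A repertoire tibble.
#' @param cutoff Frequency cutoff in (0, 1); strict inequality. Default 0.02.
#' @param productive_only Filter to productive rearrangements first.
#' @return The qualifying clone tibble (possibly empty).
#' @export
call_reactive_clones <- function(rep, cutoff = 0.02, productive_only = TRUE) {
  stopifnot(cutoff > 0, cutoff < 1)
  rep <- if (productive_only) filter_productive(rep) else as_repertoire(rep)
  stop_if_empty_repertoire(rep, "call_reactive_clones")
  rep |>
    dplyr::filter(frequency > cutoff) |>
    dplyr::arrange(dplyr::desc(frequency), cdr3_nt)
}
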