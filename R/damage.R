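#' Strand-break calling configuration
#'
#' Rules for turning backbone energy deposits and radical attacks into
#' strand breaks: a direct break requires at least `threshold_ev` of
#' cumulative deposited energy in a single backbone position; a hydroxyl-
#' radical hit produces an indirect break with probability
#' `p_radical`; two breaks on alternate strands within `window_bp` base
#' pairs form a double strand break.
#'
#' @param threshold_ev direct-break energy threshold in eV (default 17.5).
#' @param p_radical indirect-break probability per radical hit
#'   (default 0.40).
#' @param window_bp DSB pairing window in base pairs (default 10).
#' @param seed integer seed for the indirect-break draws; `NULL` uses the
#'   current RNG state.
#' @return An object of class `break_config`.
#' @export
break_config <- function(threshold_ev = 17.5, p_radical = 0.40,
                         window_bp = 10L, seed = NULL) {
  if (!is.finite(threshold_ev) || threshold_ev <= 0) {
    stop("'threshold_ev' must be > 0", call. = FALSE)
  }
  if (!is.finite(p_radical) || p_radical < 0 || p_radical > 1) {
    stop("'p_radical' must lie in [0, 1]", call. = FALSE)
  }
  window_bp <- as.integer(window_bp)
  if (is.na(window_bp) || window_bp < 1) {
    stop("'window_bp' must be >= 1", call. = FALSE)
  }
  structure(list(threshold_ev = threshold_ev, p_radical = p_radical,
                 window_bp = window_bp, seed = seed),
            class = "break_config")
}

#' Call strand breaks from backbone hits
#'
#' Direct hits accumulate deposited energy per backbone position (cell,
#' strand, base-pair index); a position with cumulative energy at or
#' above the threshold is a direct break. Each radical hit on a position
#' that is not already directly broken produces a break with the
#' configured probability; however many hits a position receives, it
#' yields at most one break. Draws are made in a fixed (sorted) position
#' order from the configured seed, so calling is reproducible.
#'
#' @param hits data frame with columns `cell_id`, `strand` (1 or 2),
#'   `bp_index` (integer `>= 0`), `kind` (`"direct"` or `"radical"`),
#'   `edep_ev` (energy for direct hits, ignored/NA for radical hits).
#' @param config a [break_config()].
#' @return Data frame of break records: `cell_id`, `strand`, `bp_index`,
#'   `origin` (`"direct"` or `"radical"`).
#' @export
call_strand_breaks <- function(hits, config = break_config()) {
  stopifnot(inherits(config, "break_config"))
  hits <- as.data.frame(hits)
  need <- c("cell_id", "strand", "bp_index", "kind")
  if (!all(need %in% names(hits))) {
    stop("hits need columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (!all(hits$strand %in% c(1L, 2L))) {
    stop("'strand' must be 1 or 2", call. = FALSE)
  }
  if (!all(hits$kind %in% c("direct", "radical"))) {
    stop("'kind' must be 'direct' or 'radical'", call. = FALSE)
  }
  if (nrow(hits) == 0L) {
    return(data.frame(cell_id = integer(), strand = integer(),
                      bp_index = integer(), origin = character(),
                      stringsAsFactors = FALSE))
  }
  e <- if ("edep_ev" %in% names(hits)) as.numeric(hits$edep_ev) else
    rep(NA_real_, nrow(hits))
  is_direct <- hits$kind == "direct"
  if (any(is_direct & (!is.finite(e) | e <= 0))) {
    stop("direct hits must carry edep_ev > 0", call. = FALSE)
  }
  key <- paste(hits$cell_id, hits$strand, hits$bp_index, sep = "\r")
  # deterministic position order for the seeded indirect draws
  pos <- data.frame(key = unique(key[order(hits$cell_id, hits$strand,
                                           hits$bp_index)]),
                    stringsAsFactors = FALSE)
  first <- match(pos$key, key)
  pos$cell_id <- hits$cell_id[first]
  pos$strand <- hits$strand[first]
  pos$bp_index <- hits$bp_index[first]
  esum <- rowsum(ifelse(is_direct, e, 0), group = key)
  nrad <- rowsum(as.numeric(!is_direct), group = key)
  pos$edep_ev <- esum[pos$key, 1L]
  pos$n_radical <- nrad[pos$key, 1L]

  direct_break <- pos$edep_ev >= config$threshold_ev
  radical_break <- rep(FALSE, nrow(pos))
  cand <- which(!direct_break & pos$n_radical > 0)
  if (length(cand)) {
    if (!is.null(config$seed)) set.seed(config$seed)
    # each radical hit is an independent Bernoulli(p); the position breaks
    # at most once
    radical_break[cand] <- stats::rbinom(length(cand),
                                         size = pos$n_radical[cand],
                                         prob = config$p_radical) > 0
  }
  broken <- direct_break | radical_break
  data.frame(cell_id = pos$cell_id[broken], strand = pos$strand[broken],
             bp_index = pos$bp_index[broken],
             origin = ifelse(direct_break[broken], "direct", "radical"),
             stringsAsFactors = FALSE)
}

#' Pair strand breaks into single and double strand breaks
#'
#' Greedy left-to-right pairing within each cell: breaks are scanned in
#' base-pair order and each unpaired break is paired with the earliest
#' unpaired break on the opposite strand no more than `window_bp` base
#' pairs away; each break is consumed at most once. Paired breaks form
#' DSBs, the remainder are SSBs. A DSB is simple (`DSB_0`) when the
#' 'window_bp'-long fragment starting at its lower break contains exactly
#' one break per strand, and complex (`DSB_*`) otherwise.
#'
#' @param breaks data frame of break records as returned by
#'   [call_strand_breaks()] (`cell_id` optional, default single cell).
#' @param window_bp pairing window in base pairs (default 10).
#' @return An object of class `strand_break_summary` with counts
#'   `n_breaks`, `ssb`, `dsb`, `dsb0`, `dsbstar`, fractions `a0`/`astar`,
#'   and the pair table.
#' @export
pair_breaks <- function(breaks, window_bp = 10L) {
  breaks <- as.data.frame(breaks)
  window_bp <- as.integer(window_bp)
  if (is.na(window_bp) || window_bp < 1) {
    stop("'window_bp' must be >= 1", call. = FALSE)
  }
  if (!all(c("strand", "bp_index") %in% names(breaks))) {
    stop("breaks need columns strand, bp_index", call. = FALSE)
  }
  if (!"cell_id" %in% names(breaks)) breaks$cell_id <- 1L
  n <- nrow(breaks)
  pairs <- NULL
  dsb0 <- 0L
  dsbstar <- 0L
  ssb <- 0L
  for (cell in unique(breaks$cell_id)) {
    b <- breaks[breaks$cell_id == cell, , drop = FALSE]
    b <- b[order(b$bp_index, b$strand), , drop = FALSE]
    m <- nrow(b)
    used <- logical(m)
    for (i in seq_len(m)) {
      if (used[i]) next
      j <- i + 1L
      while (j <= m && b$bp_index[j] - b$bp_index[i] <= window_bp) {
        if (!used[j] && b$strand[j] != b$strand[i]) {
          used[i] <- used[j] <- TRUE
          lo <- b$bp_index[i]
          # complexity: count all breaks in the fragment [lo, lo+window]
          in_frag <- b$bp_index >= lo & b$bp_index <= lo + window_bp
          per_strand <- tabulate(b$strand[in_frag], nbins = 2L)
          simple <- all(per_strand == 1L)
          if (simple) dsb0 <- dsb0 + 1L else dsbstar <- dsbstar + 1L
          pairs <- rbind(pairs, data.frame(
            cell_id = cell, bp_1 = b$bp_index[i], strand_1 = b$strand[i],
            bp_2 = b$bp_index[j], strand_2 = b$strand[j],
            class = if (simple) "DSB_0" else "DSB_*",
            stringsAsFactors = FALSE))
          break
        }
        j <- j + 1L
      }
    }
    ssb <- ssb + sum(!used)
  }
  dsb <- dsb0 + dsbstar
  structure(list(
    n_breaks = n, ssb = ssb, dsb = dsb, dsb0 = dsb0, dsbstar = dsbstar,
    a0 = if (dsb > 0) dsb0 / dsb else NA_real_,
    astar = if (dsb > 0) dsbstar / dsb else NA_real_,
    pairs = pairs, window_bp = window_bp
  ), class = "strand_break_summary")
}

#' @export
print.strand_break_summary <- function(x, ...) {
  cat(sprintf(
    "Strand breaks: %d total -> %d SSB, %d DSB (%d simple DSB_0, %d complex DSB_*)\n",
    x$n_breaks, x$ssb, x$dsb, x$dsb0, x$dsbstar))
  if (x$dsb > 0) {
    cat(sprintf("  fractions a0 = %.3f, a* = %.3f\n", x$a0, x$astar))
  }
  invisible(x)
}

#' DSB counts with complexity split
#'
#' @param dsb0 number of simple DSBs (exactly one break per strand in the
#'   pairing window).
#' @param dsbstar number of complex DSBs.
#' @return An object of class `dsb_counts` with totals and fractions
#'   `a0`, `astar` (summing to 1 when any DSB exists).
#' @export
dsb_counts <- function(dsb0, dsbstar) {
  if (dsb0 < 0 || dsbstar < 0) {
    stop("DSB counts must be >= 0", call. = FALSE)
  }
  dsb <- dsb0 + dsbstar
  structure(list(dsb = dsb, dsb0 = dsb0, dsbstar = dsbstar,
                 a0 = if (dsb > 0) dsb0 / dsb else NA_real_,
                 astar = if (dsb > 0) dsbstar / dsb else NA_real_),
            class = "dsb_counts")
}
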