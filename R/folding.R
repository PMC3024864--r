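#' Additive base-pair energy model
#'
#' The internal folding engine scores a secondary structure as the sum of
#' its base-pair energies; there are no stacking or loop terms. This keeps
#' every downstream feature reproducible without external thermodynamic
#' software, while preserving the qualitative ordering that GC pairs are
#' stronger than AU, which are stronger than GU wobble pairs.
#'
#' @param gc,au,gu Pair energies in kcal/mol (must be <= 0).
#' @param min_hairpin_loop Minimum number of unpaired bases in a hairpin
#'   loop (default 3, the standard folding convention).
#' @param temperature Temperature in Kelvin (default 310.15, i.e. 37 C).
#' @return Object of class `energy_model`.
#' @export
energy_model <- function(gc = -3, au = -2, gu = -1,
                         min_hairpin_loop = 3L, temperature = 310.15) {
  stopifnot(gc <= 0, au <= 0, gu <= 0, min_hairpin_loop >= 1,
            temperature > 0)
  structure(list(
    gc = gc, au = au, gu = gu,
    min_hairpin_loop = as.integer(min_hairpin_loop),
    temperature = temperature,
    gas_constant = 0.0019872  # kcal/(mol K)
  ), class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat(sprintf(
    "<energy_model> GC=%g AU=%g GU=%g kcal/mol, min loop %d, T=%g K\n",
    x$gc, x$au, x$gu, x$min_hairpin_loop, x$temperature))
  invisible(x)
}

rt_of <- function(model) model$gas_constant * model$temperature

encode_seq <- function(seq) {
  match(strsplit(seq, "", fixed = TRUE)[[1]], c("A", "C", "G", "U")) - 1L
}

partner_to_dotbracket <- function(partner) {
  out <- rep(".", length(partner))
  out[partner > seq_along(partner)] <- "("
  out[partner != 0L & partner < seq_along(partner)] <- ")"
  paste(out, collapse = "")
}

#' Predict the minimum free energy structure
#'
#' Dynamic programming over all nested structures with hairpin loops of at
#' least `min_hairpin_loop` unpaired bases; allowed pairs are AU, GC and
#' the GU wobble. Co-optimal structures are resolved deterministically
#' (pairing the left end is preferred over leaving it unpaired; the
#' smallest partner index wins). An unpairable sequence yields the open
#' chain with MFE 0.
#'
#' @param record A [sequence_record()] or a plain sequence string.
#' @param model An [energy_model()].
#' @return List with `structure` (dot-bracket) and `mfe` (kcal/mol).
#' @export
fold_mfe <- function(record, model = energy_model()) {
  record <- as_sequence_record(record)
  res <- fold_mfe_cpp(encode_seq(record$seq), model$gc, model$au, model$gu,
                      model$min_hairpin_loop)
  list(structure = partner_to_dotbracket(res$partner), mfe = res$mfe)
}

#' Fold a sequence and compute ensemble thermodynamics
#'
#' Computes the Boltzmann partition function Z over all legal structures,
#' the ensemble free energy EFE = -RT log Z, the probability `freq` of the
#' MFE structure in the ensemble, base-pair probabilities by an
#' inside-outside recursion, and the ensemble diversity
#' 2 * sum_(i<j) p_ij (1 - p_ij) (expected base-pair distance).
#'
#' @inheritParams fold_mfe
#' @return Object of class `fold_result` with fields `structure`, `mfe`,
#'   `efe`, `freq`, `diversity`, `bp_probs` (data frame `i`, `j`, `prob`
#'   of nonzero entries, 1-based) and `log_z`.
#' @export
partition_function <- function(record, model = energy_model()) {
  record <- as_sequence_record(record)
  codes <- encode_seq(record$seq)
  mfe_res <- fold_mfe_cpp(codes, model$gc, model$au, model$gu,
                          model$min_hairpin_loop)
  pf <- partition_function_cpp(codes, model$gc, model$au, model$gu,
                               model$min_hairpin_loop, rt_of(model))
  p <- pf$bp_probs
  idx <- which(p > 0, arr.ind = TRUE)
  bp <- data.frame(
    i = as.integer(idx[, 1]), j = as.integer(idx[, 2]),
    prob = p[idx]
  )
  bp <- bp[order(bp$i, bp$j), , drop = FALSE]
  rownames(bp) <- NULL
  structure(list(
    structure = partner_to_dotbracket(mfe_res$partner),
    mfe = mfe_res$mfe,
    efe = -rt_of(model) * log(pf$z),
    freq = exp(-mfe_res$mfe / rt_of(model)) / pf$z,
    diversity = 2 * sum(bp$prob * (1 - bp$prob)),
    bp_probs = bp,
    log_z = log(pf$z)
  ), class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(sprintf("<fold_result> MFE=%.3f EFE=%.3f Freq=%.3g diversity=%.3f\n%s\n",
              x$mfe, x$efe, x$freq, x$diversity, x$structure))
  invisible(x)
}

#' Parse a dot-bracket string into base pairs
#'
#' @param structure String over `(`, `)` and `.` (Vienna convention).
#' @return Integer matrix with columns `i`, `j` (1-based, i < j), one row
#'   per pair, ordered by `i`.
#' @export
parse_dot_bracket <- function(structure) {
  stopifnot(is.character(structure), length(structure) == 1L)
  chars <- strsplit(structure, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c("(", ")", "."))
  if (length(bad) > 0L)
    stop(sprintf("structure parse error: invalid character '%s' at position %d",
                 chars[bad[1]], bad[1]), call. = FALSE)
  open <- integer(0)
  pairs <- matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("i", "j")))
  for (pos in seq_along(chars)) {
    if (chars[pos] == "(") {
      open <- c(open, pos)
    } else if (chars[pos] == ")") {
      if (length(open) == 0L)
        stop(sprintf("structure parse error: unmatched ')' at position %d", pos),
             call. = FALSE)
      pairs <- rbind(pairs, c(open[length(open)], pos))
      open <- open[-length(open)]
    }
  }
  if (length(open) > 0L)
    stop(sprintf(
      "structure parse error: %d unclosed '(' at end of string (first at position %d)",
      length(open), open[1]), call. = FALSE)
  pairs[order(pairs[, 1]), , drop = FALSE]
}

#' Structural counts for a folded sequence
#'
#' Derives base-pair, stem and loop counts from a dot-bracket structure.
#' A stem is a maximal run of stacked pairs ((i, j) and (i+1, j-1) belong
#' to the same stem); a loop is a hairpin (terminal) loop, i.e. a pair
#' enclosing no other pair, so single hairpins have `n_loops = 1` and
#' multi-branched structures have `n_loops >= 2`. Each pair is classified
#' by its unordered nucleotide set (AU, GC or GU); any other paired
#' combination is an inconsistent structure.
#'
#' @inheritParams fold_mfe
#' @param structure Dot-bracket string of the same length as the sequence.
#' @return Object of class `structure_stats` with `pairs`, `n_bp`,
#'   `n_stems`, `n_loops`, and `pair_type_counts` (named AU/GC/GU).
#' @export
structure_stats <- function(record, structure) {
  record <- as_sequence_record(record)
  if (nchar(structure) != record$length)
    stop("structure length does not match sequence length", call. = FALSE)
  pairs <- parse_dot_bracket(structure)
  n_bp <- nrow(pairs)
  chars <- strsplit(record$seq, "", fixed = TRUE)[[1]]
  counts <- c(AU = 0L, GC = 0L, GU = 0L)
  if (n_bp > 0L) {
    key <- apply(pairs, 1L, function(p) {
      paste(sort(c(chars[p[1]], chars[p[2]])), collapse = "")
    })
    type <- c(AU = "AU", CG = "GC", GU = "GU")[key]
    if (anyNA(type)) {
      bad <- which(is.na(type))[1]
      stop(sprintf(
        "inconsistent structure: positions %d-%d pair %s-%s is not a legal base pair",
        pairs[bad, 1], pairs[bad, 2], chars[pairs[bad, 1]], chars[pairs[bad, 2]]),
        call. = FALSE)
    }
    tab <- table(factor(type, levels = c("AU", "GC", "GU")))
    counts <- c(AU = as.integer(tab[["AU"]]), GC = as.integer(tab[["GC"]]),
                GU = as.integer(tab[["GU"]]))
  }
  has_pair <- function(i, j) {
    any(pairs[, 1] == i & pairs[, 2] == j)
  }
  n_stems <- 0L
  n_loops <- 0L
  if (n_bp > 0L) {
    paired <- logical(nchar(structure))
    paired[pairs] <- TRUE
    for (r in seq_len(n_bp)) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      if (!has_pair(i - 1L, j + 1L)) n_stems <- n_stems + 1L
      if (j - i < 2L || !any(paired[(i + 1L):(j - 1L)])) n_loops <- n_loops + 1L
    }
  }
  structure(list(pairs = pairs, n_bp = n_bp, n_stems = n_stems,
                 n_loops = n_loops, pair_type_counts = counts),
            class = "structure_stats")
}

#' @export
print.structure_stats <- function(x, ...) {
  cat(sprintf("<structure_stats> %d bp, %d stems, %d loops (AU=%d GC=%d GU=%d)\n",
              x$n_bp, x$n_stems, x$n_loops,
              x$pair_type_counts[["AU"]], x$pair_type_counts[["GC"]],
              x$pair_type_counts[["GU"]]))
  invisible(x)
}
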