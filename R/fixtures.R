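# Stem-loop construction with a provable fold topology under the additive
# energy model. The 5' arm uses purines only (G/A), the 3' arm the
# complementary pyrimidines (C/U), the terminal loop is all-C and bulges
# are A on the 5' side. Consequently every legal base pair runs from the
# left half (5' arm) to the right half (loop C / 3' arm), so any two
# pairs are nested and every legal structure — in particular the MFE
# structure — contains exactly one hairpin loop.
build_stem_loop <- function(stem_len, loop_len, bulge_prob, gc_frac) {
  arm5 <- sample(c("G", "A"), stem_len, replace = TRUE,
                 prob = c(gc_frac, 1 - gc_frac))
  arm3 <- rev(c(G = "C", A = "U")[arm5])
  left <- character(0)
  for (s in seq_len(stem_len)) {
    left <- c(left, arm5[s])
    if (runif(1) < bulge_prob) left <- c(left, "A")  # 5'-side bulge
  }
  paste(c(left, rep("C", loop_len), arm3), collapse = "")
}

#' Generate a hairpin-like positive sequence
#'
#' Samples a GC-biased stem of exact complementary pairs (purine 5' arm,
#' pyrimidine 3' arm) with optional 5'-side bulges, an all-C terminal
#' loop, and short unpaired flanks (A before, C after). The letter layout
#' makes every legal base pair run from the 5' half to the 3' half, so
#' under the additive [energy_model()] the MFE structure is guaranteed to
#' be a single-loop hairpin — the signature of a real precursor.
#'
#' @param stem_range Integer range of stem lengths in base pairs.
#' @param loop_range Integer range of terminal loop lengths.
#' @param bulge_prob Per-stack probability of inserting a one-base bulge.
#' @param flank_range Integer range of unpaired flank lengths (each side).
#' @param gc_frac Fraction of GC pairs in the stem (the rest are AU).
#' @param id Record identifier.
#' @return A [sequence_record()]. Randomness comes from the global RNG;
#'   seed with `set.seed()` or use [make_dataset()].
#' @export
make_hairpin <- function(stem_range = c(30L, 55L), loop_range = c(4L, 8L),
                         bulge_prob = 0.1, flank_range = c(0L, 5L),
                         gc_frac = 0.6, id = "hairpin") {
  stopifnot(stem_range[1] >= 4L, loop_range[1] >= 3L)
  stem_len <- sample(stem_range[1]:stem_range[2], 1L)
  loop_len <- sample(loop_range[1]:loop_range[2], 1L)
  core <- build_stem_loop(stem_len, loop_len, bulge_prob, gc_frac)
  flank <- function(letter) {
    paste(rep(letter, sample(flank_range[1]:flank_range[2], 1L)),
          collapse = "")
  }
  sequence_record(id, paste0(flank("A"), core, flank("C")))
}

#' Generate a pseudo-hairpin negative sequence
#'
#' With probability `multi_branch`, concatenates two or three short
#' stem-loops separated by unpairable spacers (a multi-branched
#' construction, mirroring the observation that the large majority of
#' pseudo precursors fold with multiple loops); otherwise emits an
#' i.i.d. uniform random sequence. Lengths are padded into `length_range`
#' with unpairable residues.
#'
#' @param length_range Target sequence length range in nt (default
#'   70-150, the hairpin-candidate window).
#' @param multi_branch Probability of the multi-branched construction
#'   (default 0.84).
#' @param branch_stem_range,branch_loop_range Stem/loop length ranges of
#'   each short branch.
#' @param gc_frac Fraction of GC pairs in branch stems.
#' @param id Record identifier.
#' @return A [sequence_record()].
#' @export
make_pseudo <- function(length_range = c(70L, 150L), multi_branch = 0.84,
                        branch_stem_range = c(8L, 14L),
                        branch_loop_range = c(4L, 7L),
                        gc_frac = 0.5, id = "pseudo") {
  if (runif(1) < multi_branch) {
    n_branch <- sample(2:3, 1L)
    pieces <- character(0)
    for (b in seq_len(n_branch)) {
      stem <- sample(branch_stem_range[1]:branch_stem_range[2], 1L)
      loop <- sample(branch_loop_range[1]:branch_loop_range[2], 1L)
      pieces <- c(pieces, build_stem_loop(stem, loop, 0, gc_frac))
      if (b < n_branch)
        pieces <- c(pieces, paste(sample(c("A", "C"), sample(2:6, 1L),
                                         replace = TRUE), collapse = ""))
    }
    seq <- paste(pieces, collapse = "")
    target <- sample(length_range[1]:length_range[2], 1L)
    if (nchar(seq) < target) {
      pad <- target - nchar(seq)
      head_pad <- sample.int(pad + 1L, 1L) - 1L
      seq <- paste0(
        paste(sample(c("A", "C"), head_pad, replace = TRUE), collapse = ""),
        seq,
        paste(sample(c("A", "C"), pad - head_pad, replace = TRUE),
              collapse = ""))
    }
  } else {
    len <- sample(length_range[1]:length_range[2], 1L)
    seq <- paste(sample(c("A", "C", "G", "U"), len, replace = TRUE),
                 collapse = "")
  }
  sequence_record(id, seq)
}

#' Generate a labeled synthetic hairpin dataset
#'
#' `n_pos` hairpin-like positives and `round(ratio * n_pos)` pseudo
#' negatives, honoring the requested class imbalance within rounding. The
#' default ratio 7.79 matches the negative:positive imbalance of the
#' reference training collection; the default multi-branch fraction 0.84
#' matches the fraction of pseudo hairpins folding with multiple loops.
#'
#' @param n_pos Number of positives.
#' @param ratio Negative:positive ratio (default 7.79).
#' @param multi_branch Multi-branch fraction for negatives.
#' @param seed Integer seed (global RNG state is left untouched).
#' @param ... Additional arguments split between [make_hairpin()]
#'   (`stem_range`, `loop_range`, `bulge_prob`) and [make_pseudo()]
#'   (`length_range`, `branch_stem_range`, `branch_loop_range`).
#' @return List with `records` (sequence records, positives first) and
#'   `labels` (+1/-1).
#' @export
make_dataset <- function(n_pos, ratio = 7.79, multi_branch = 0.84,
                         seed = 1L, ...) {
  stopifnot(n_pos >= 1L)
  n_neg <- round(ratio * n_pos)
  dots <- list(...)
  pos_args <- dots[intersect(names(dots),
                             c("stem_range", "loop_range", "bulge_prob",
                               "flank_range"))]
  neg_args <- dots[intersect(names(dots),
                             c("length_range", "branch_stem_range",
                               "branch_loop_range"))]
  withr::with_seed(seed, {
    pos <- lapply(seq_len(n_pos), function(i) {
      do.call(make_hairpin, c(list(id = sprintf("real%04d", i)), pos_args))
    })
    neg <- lapply(seq_len(n_neg), function(i) {
      do.call(make_pseudo, c(list(id = sprintf("pseudo%04d", i),
                                  multi_branch = multi_branch), neg_args))
    })
    list(records = c(pos, neg),
         labels = rep(c(1L, -1L), c(n_pos, n_neg)))
  })
}

#' Generate a linearly separable synthetic feature table
#'
#' Informative columns are drawn from class-shifted normal distributions
#' (positive class mean `effect_size`, negative class mean 0, unit
#' variance); the remaining columns are pure noise in both classes. This
#' is the test bed for feature selection and the ensemble: with a large
#' effect size the classes are separable and a correct pipeline should
#' recover near-perfect geometric-mean performance.
#'
#' @param n_pos,n_neg Class sizes (>= 4 each).
#' @param effect_size Class-mean shift of informative columns, in units of
#'   the within-class standard deviation (default 3).
#' @param n_informative Number of informative columns (the first columns).
#' @param n_features Total number of columns (default 65, mirroring the
#'   real feature space).
#' @param seed Integer seed.
#' @return A labeled [feature_matrix()] with columns `f01`, `f02`, ...
#' @export
make_separable_table <- function(n_pos, n_neg, effect_size = 3,
                                 n_informative = 10L, n_features = 65L,
                                 seed = 1L) {
  stopifnot(n_pos >= 4L, n_neg >= 4L, n_informative >= 1L,
            n_informative <= n_features)
  withr::with_seed(seed, {
    n <- n_pos + n_neg
    labels <- rep(c(1L, -1L), c(n_pos, n_neg))
    x <- matrix(rnorm(n * n_features), nrow = n)
    shift <- ifelse(labels == 1L, effect_size, 0)
    for (jcol in seq_len(n_informative)) x[, jcol] <- x[, jcol] + shift
    colnames(x) <- sprintf("f%02d", seq_len(n_features))
    feature_matrix(x, labels = labels,
                   ids = c(sprintf("real%04d", seq_len(n_pos)),
                           sprintf("pseudo%04d", seq_len(n_neg))))
  })
}
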