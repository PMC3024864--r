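TRIPLET_PATTERNS <- c("(((", "((.", "(..", "(.(", ".((", ".(.", "..(", "...")

# Xia et al. (1998) Watson-Crick nearest-neighbour stack enthalpies
# (kcal/mol), keyed by 5'-XY-3' of the top strand; the bottom strand is
# implied by complementarity. Stacks involving a GU wobble pair are not in
# this table and use a single generic enthalpy (see GU_STACK_DH).
WC_STACK_DH <- c(
  AA = -6.82, AU = -9.38, UA = -7.69, CU = -10.48, CA = -10.44,
  GU = -11.40, GA = -12.44, CG = -10.64, GG = -13.39, GC = -14.88,
  # symmetric completions (a stack equals its reverse-complement stack)
  UU = -6.82, UG = -10.44, AG = -10.48, AC = -11.40, UC = -12.44,
  CC = -13.39
)
GU_STACK_DH <- -8.0

#' Canonical feature names
#'
#' The fixed, ordered list of the 65 feature names: 32 triplet
#' structure-sequence elements, 15 base-pair features (including the four
#' multi-loop features normalized by the loop count), and 18 thermodynamic
#' features. This ordering is used for every feature table and TSV header.
#'
#' @param group Optional subset: `"triplet"`, `"base_pair"` or
#'   `"thermodynamic"`.
#' @return Character vector of feature names.
#' @export
feature_names <- function(group = c("all", "triplet", "base_pair",
                                    "thermodynamic")) {
  group <- match.arg(group)
  triplet <- as.vector(t(outer(c("A", "C", "G", "U"), TRIPLET_PATTERNS,
                               paste0)))
  base_pair <- c(
    "G/C_ratio", "%C+G", "dP", "Avg_BP_Stem", "Diversity",
    "|A-U|/L", "|G-C|/L", "|G-U|/L",
    "(A-U)/n_stems", "(G-C)/n_stems", "(G-U)/n_stems",
    "dP/n_loops", "%(A-U)/n_loops", "%(G-C)/n_loops", "%(G-U)/n_loops"
  )
  thermo <- c(
    "dG", "MFEI_1", "MFEI_2", "MFEI_3", "MFEI_4", "Freq",
    "NEFE", "Diff", "dH", "dS", "Tm", "dH/L", "dS/L", "Tm/L",
    "p-value_MFE", "p-value_EFE", "z-score_MFE", "z-score_EFE"
  )
  switch(group,
         all = c(triplet, base_pair, thermo),
         triplet = triplet,
         base_pair = base_pair,
         thermodynamic = thermo)
}

#' Feature group tags aligned with [feature_names()]
#'
#' @return Character vector of length 65 over
#'   \{triplet, base_pair, thermodynamic\}.
#' @export
feature_groups <- function() {
  rep(c("triplet", "base_pair", "thermodynamic"), times = c(32L, 15L, 18L))
}

guarded <- function(num, den) if (den == 0) 0 else num / den

#' Triplet structure-sequence features
#'
#' For each of the L-2 windows of three adjacent positions, the pairing
#' pattern (brackets collapsed to `(`, i.e. paired/unpaired only) combined
#' with the middle nucleotide gives one of 32 categories; counts are
#' normalized by L-2 so the 32 frequencies sum to 1.
#'
#' @inheritParams structure_stats
#' @return Named numeric vector of 32 frequencies.
#' @export
triplet_features <- function(record, structure) {
  record <- as_sequence_record(record)
  if (record$length < 3L)
    stop("triplet features require a sequence of length >= 3", call. = FALSE)
  if (nchar(structure) != record$length)
    stop("structure length does not match sequence length", call. = FALSE)
  parse_dot_bracket(structure)  # validates balance
  collapsed <- chartr(")", "(", structure)
  schars <- strsplit(collapsed, "", fixed = TRUE)[[1]]
  nchars <- strsplit(record$seq, "", fixed = TRUE)[[1]]
  counts <- stats::setNames(numeric(32), feature_names("triplet"))
  for (mid in 2:(record$length - 1L)) {
    key <- paste0(nchars[mid], paste(schars[(mid - 1L):(mid + 1L)],
                                     collapse = ""))
    counts[[key]] <- counts[[key]] + 1
  }
  counts / (record$length - 2L)
}

#' Base-pair (secondary structure) features
#'
#' The 11 classic structure features plus the four multi-loop features
#' normalized by the hairpin-loop count. `dP = n_bp / L` is the base-pair
#' density; `%(X-Y)` is the fraction of X-Y pairs among all base pairs;
#' zero denominators (no stems, loops, pairs, or C residues) resolve to 0
#' so unpairable inputs still yield finite vectors.
#'
#' @inheritParams fold_mfe
#' @param stats A [structure_stats()] object for the same structure.
#' @param fold A [partition_function()] result for the same sequence.
#' @return Named numeric vector of 15 values.
#' @export
base_pair_features <- function(record, stats, fold) {
  record <- as_sequence_record(record)
  L <- record$length
  chars <- strsplit(record$seq, "", fixed = TRUE)[[1]]
  nG <- sum(chars == "G"); nC <- sum(chars == "C")
  cnt <- stats$pair_type_counts
  dP <- stats$n_bp / L
  pct <- function(xy) guarded(cnt[[xy]], stats$n_bp)
  vals <- c(
    guarded(nG, nC),
    100 * (nC + nG) / L,
    dP,
    guarded(stats$n_bp, stats$n_stems),
    fold$diversity,
    cnt[["AU"]] / L,
    cnt[["GC"]] / L,
    cnt[["GU"]] / L,
    guarded(cnt[["AU"]], stats$n_stems),
    guarded(cnt[["GC"]], stats$n_stems),
    guarded(cnt[["GU"]], stats$n_stems),
    guarded(dP, stats$n_loops),
    guarded(pct("AU"), stats$n_loops),
    guarded(pct("GC"), stats$n_loops),
    guarded(pct("GU"), stats$n_loops)
  )
  stats::setNames(vals, feature_names("base_pair"))
}

# Nearest-neighbour stack enthalpy over consecutive stacked pairs.
stack_enthalpy <- function(chars, pairs) {
  if (nrow(pairs) == 0L) return(0)
  dh <- 0
  key <- paste(pairs[, 1], pairs[, 2])
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    if (!(paste(i + 1L, j - 1L) %in% key)) next  # no stack on top of (i,j)
    p1 <- c(chars[i], chars[j])
    p2 <- c(chars[i + 1L], chars[j - 1L])
    wobble <- function(p) all(sort(p) == c("G", "U"))
    if (wobble(p1) || wobble(p2)) {
      dh <- dh + GU_STACK_DH
    } else {
      dh <- dh + WC_STACK_DH[[paste0(chars[i], chars[i + 1L])]]
    }
  }
  dh
}

#' Thermodynamic features
#'
#' MFE-derived indices (`dG = MFE/L`, the MFEI family), ensemble
#' quantities (`NEFE = EFE/L`, `Freq`, `Diff = |MFE - EFE|/L`),
#' enthalpy/entropy/melting-temperature estimates from nearest-neighbour
#' stack enthalpies (`dS = (dH - MFE) * 1000 / T` in cal/(mol K),
#' `Tm = 1000 * dH / dS - 273.15` in degrees C, plus per-length versions),
#' and the four shuffle-null statistics (z-scores and empirical p-values
#' of MFE and EFE).
#'
#' By default `MFEI_3 = dG / n_loops` and `MFEI_4 = MFE / n_bp`; set
#' `mfei34 = "swapped"` to exchange the two denominators (the literature
#' is ambiguous about which index carries the loop normalization).
#'
#' @inheritParams base_pair_features
#' @param null A [null_statistics()] result computed with the same engine.
#' @param mfei34 `"loops_bp"` (default) or `"swapped"`.
#' @param model The [energy_model()] used for folding (temperature feeds
#'   the entropy estimate).
#' @return Named numeric vector of 18 values.
#' @export
thermo_features <- function(record, stats, fold, null,
                            model = energy_model(),
                            mfei34 = c("loops_bp", "swapped")) {
  record <- as_sequence_record(record)
  mfei34 <- match.arg(mfei34)
  L <- record$length
  chars <- strsplit(record$seq, "", fixed = TRUE)[[1]]
  pct_cg <- 100 * sum(chars %in% c("C", "G")) / L
  dG <- fold$mfe / L
  mfei_loops <- guarded(dG, stats$n_loops)
  mfei_bp <- guarded(fold$mfe, stats$n_bp)
  if (mfei34 == "swapped") {
    tmp <- mfei_loops; mfei_loops <- mfei_bp; mfei_bp <- tmp
  }
  dH <- stack_enthalpy(chars, stats$pairs)
  dS <- (dH - fold$mfe) * 1000 / model$temperature
  Tm <- if (dS == 0) 0 else 1000 * dH / dS - 273.15
  zp_mfe <- z_and_p(fold$mfe, null$null_mfe)
  zp_efe <- z_and_p(fold$efe, null$null_efe)
  vals <- c(
    dG,
    guarded(dG, pct_cg),
    guarded(dG, stats$n_stems),
    mfei_loops,
    mfei_bp,
    fold$freq,
    fold$efe / L,
    abs(fold$mfe - fold$efe) / L,
    dH, dS, Tm, dH / L, dS / L, Tm / L,
    zp_mfe$p, zp_efe$p, zp_mfe$z, zp_efe$z
  )
  stats::setNames(vals, feature_names("thermodynamic"))
}

#' Extract the full 65-dimensional feature vector for one sequence
#'
#' Folds the sequence, derives structural counts, generates the
#' dinucleotide-shuffle null, and assembles the canonical feature vector
#' (triplet block, base-pair block, thermodynamic block).
#'
#' @inheritParams fold_mfe
#' @param n_shuffles Shuffles for the null distributions (default 300).
#' @param seed Integer seed for the shuffle null.
#' @param mfei34 Passed to [thermo_features()].
#' @return Named numeric vector of length 65 with attribute `group`.
#' @export
extract_all <- function(record, model = energy_model(), n_shuffles = 300L,
                        seed = 1L, mfei34 = "loops_bp") {
  record <- as_sequence_record(record)
  fold <- partition_function(record, model)
  stats <- structure_stats(record, fold$structure)
  null <- null_statistics(record, model, n = n_shuffles, seed = seed)
  out <- c(
    triplet_features(record, fold$structure),
    base_pair_features(record, stats, fold),
    thermo_features(record, stats, fold, null, model = model,
                    mfei34 = mfei34)
  )
  stopifnot(identical(names(out), feature_names()), all(is.finite(out)))
  attr(out, "group") <- feature_groups()
  out
}

#' Assemble a feature matrix
#'
#' A feature matrix bundles a numeric matrix of feature values (rows =
#' sequences, columns = named features), optional class labels (+1 real,
#' -1 pseudo), and row ids. All classifier and evaluation functions
#' consume this container.
#'
#' @param x Numeric matrix (or data frame) of feature values with column
#'   names.
#' @param labels Optional integer vector over \{+1, -1\}.
#' @param ids Optional character vector of row ids.
#' @return Object of class `feature_matrix`.
#' @export
feature_matrix <- function(x, labels = NULL, ids = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) stop("feature matrix requires column names",
                                 call. = FALSE)
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != nrow(x))
      stop("labels length must match number of rows", call. = FALSE)
    if (!all(labels %in% c(1L, -1L)))
      stop("labels must be +1 (real) or -1 (pseudo)", call. = FALSE)
  }
  if (is.null(ids)) ids <- sprintf("s%04d", seq_len(nrow(x)))
  ids <- as.character(ids)
  rownames(x) <- ids
  structure(list(x = x, labels = labels, ids = ids),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  lab <- if (is.null(x$labels)) "unlabeled" else
    sprintf("%d positive / %d negative", sum(x$labels == 1L),
            sum(x$labels == -1L))
  cat(sprintf("<feature_matrix> %d x %d (%s)\n", nrow(x$x), ncol(x$x), lab))
  invisible(x)
}

# Deterministic per-record seed derived from the batch seed and the
# sequence content, so batch extraction is invariant to record order.
record_seed <- function(seed, record) {
  codes <- utf8ToInt(record$seq)
  h <- sum(codes * (seq_along(codes) %% 97L + 1L)) %% 1000003L
  as.integer((as.double(seed) * 1009 + h) %% 2147483647)
}

#' Extract features for a batch of sequence records
#'
#' Per-record shuffle seeds are derived deterministically from `seed` and
#' the record's sequence, so results are invariant to record order and
#' reproducible across runs.
#'
#' @param records List of [sequence_record()] objects.
#' @param labels Optional labels (+1/-1), one per record.
#' @inheritParams extract_all
#' @return A [feature_matrix()].
#' @export
extract_features <- function(records, labels = NULL, model = energy_model(),
                             n_shuffles = 300L, seed = 1L,
                             mfei34 = "loops_bp") {
  records <- lapply(records, as_sequence_record)
  rows <- lapply(seq_along(records), function(i) {
    extract_all(records[[i]], model = model, n_shuffles = n_shuffles,
                seed = record_seed(seed, records[[i]]), mfei34 = mfei34)
  })
  x <- do.call(rbind, rows)
  colnames(x) <- feature_names()
  feature_matrix(x, labels = labels,
                 ids = vapply(records, `[[`, character(1), "id"))
}

#' Write a feature matrix as TSV
#'
#' First column `id`, then (if present) `label`, then the 65 canonical
#' feature columns; header row mandatory.
#'
#' @param fm A [feature_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_tsv <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- data.frame(id = fm$ids, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(fm$labels)) df$label <- fm$labels
  df <- cbind(df, as.data.frame(fm$x, check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix from TSV
#'
#' @param path Path to a TSV written by [write_feature_tsv()].
#' @return A [feature_matrix()].
#' @export
read_feature_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"id" %in% names(df)) stop("feature TSV lacks an 'id' column",
                                 call. = FALSE)
  labels <- if ("label" %in% names(df)) df$label else NULL
  keep <- setdiff(names(df), c("id", "label"))
  feature_matrix(as.matrix(df[keep]), labels = labels, ids = df$id)
}
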