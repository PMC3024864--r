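#' Dinucleotide-preserving sequence shuffle
#'
#' Euler-path shuffle in the Altschul-Erickson style: the sequence is
#' viewed as a walk on the graph whose vertices are nucleotides and whose
#' edges are the observed dinucleotides; a random Eulerian rearrangement
#' of the edges yields a shuffled sequence with exactly the same
#' mononucleotide and dinucleotide count multisets, and the same first and
#' last nucleotide. Randomness is drawn from R's global RNG; call
#' `set.seed()` (or use [null_statistics()]) for reproducibility.
#'
#' @param seq RNA sequence string (length >= 2).
#' @return Shuffled sequence string.
#' @export
dinuc_shuffle <- function(seq) {
  chars <- strsplit(normalize_sequence(seq), "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < 2L) stop("dinuc_shuffle requires a sequence of length >= 2",
                   call. = FALSE)
  first <- chars[1]
  last <- chars[n]
  # outgoing edge multisets
  edges <- split(chars[-1], chars[-n])
  verts <- names(edges)
  # Sample the designated last outgoing edge of every vertex other than the
  # terminal one; accept when these edges form paths that all lead to the
  # terminal vertex (an arborescence), which guarantees an Eulerian walk
  # exists with those edges used last. Rejection sampling is cheap on a
  # 4-letter alphabet.
  need_last <- setdiff(verts, last)
  last_edge <- character(0)
  if (length(need_last) > 0L) {
    repeat {
      last_edge <- vapply(need_last, function(v) {
        pool <- edges[[v]]
        pool[sample.int(length(pool), 1L)]
      }, character(1))
      ok <- TRUE
      for (v in need_last) {
        cur <- v
        seen <- character(0)
        while (cur != last) {
          if (cur %in% seen || !(cur %in% need_last)) { ok <- FALSE; break }
          seen <- c(seen, cur)
          cur <- last_edge[[cur]]
        }
        if (!ok) break
      }
      if (ok) break
    }
  }
  # Shuffle the remaining edges of each vertex; append the designated last
  # edge at the end of its list.
  for (v in verts) {
    pool <- edges[[v]]
    if (v %in% need_last) {
      drop <- match(last_edge[[v]], pool)
      pool <- pool[-drop]
    }
    if (length(pool) > 1L) pool <- pool[sample.int(length(pool))]
    if (v %in% need_last) pool <- c(pool, last_edge[[v]])
    edges[[v]] <- pool
  }
  # Walk the Euler path.
  out <- character(n)
  out[1] <- first
  cur <- first
  ptr <- stats::setNames(rep(1L, length(verts)), verts)
  for (i in 2L:n) {
    nxt <- edges[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}

#' Folding-energy null distribution from dinucleotide shuffles
#'
#' Generates `n` dinucleotide-preserving shuffles of the input and folds
#' each with the same engine and energy model as the original, recording
#' MFE and EFE per shuffle. These null distributions feed the z-score and
#' empirical p-value features.
#'
#' @inheritParams fold_mfe
#' @param n Number of shuffles (default 300; smaller values such as 25 are
#'   adequate for quick runs).
#' @param seed Integer seed; the global RNG state is left untouched.
#' @return Object of class `shuffle_null` with `n_shuffles`, `null_mfe`,
#'   `null_efe` and `seed`.
#' @export
null_statistics <- function(record, model = energy_model(), n = 300L,
                            seed = 1L) {
  record <- as_sequence_record(record)
  if (n < 2L) stop("null_statistics requires n >= 2", call. = FALSE)
  shuffles <- withr::with_seed(seed, {
    replicate(n, dinuc_shuffle(record$seq))
  })
  null_mfe <- numeric(n)
  null_efe <- numeric(n)
  for (i in seq_len(n)) {
    fr <- partition_function(sequence_record(paste0(record$id, "_shuf", i),
                                             shuffles[i]), model)
    null_mfe[i] <- fr$mfe
    null_efe[i] <- fr$efe
  }
  structure(list(n_shuffles = as.integer(n), null_mfe = null_mfe,
                 null_efe = null_efe, seed = as.integer(seed)),
            class = "shuffle_null")
}

#' z-score and empirical p-value against a null distribution
#'
#' `z = (observed - mean(null)) / sd(null)` with the n-1 denominator for
#' the standard deviation (`z = 0` when the null is degenerate), and the
#' add-one lower-tail empirical p-value
#' `p = (#\{null <= observed\} + 1) / (n + 1)`, which is never exactly 0.
#' The lower tail is used because real precursors have unusually low
#' folding energies.
#'
#' @param observed Observed statistic (kcal/mol).
#' @param null Numeric vector of null statistics (non-empty).
#' @return List with `z` and `p`.
#' @export
z_and_p <- function(observed, null) {
  stopifnot(is.numeric(observed), length(observed) == 1L,
            is.numeric(null), length(null) >= 1L)
  s <- if (length(null) > 1L) sd(null) else 0
  z <- if (is.na(s) || s == 0) 0 else (observed - mean(null)) / s
  p <- (sum(null <= observed) + 1) / (length(null) + 1)
  list(z = z, p = p)
}
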