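# Alignment-column conservation scoring and consensus patterns.
#
# Three scoring families are offered: Shannon entropy, mean pairwise
# substitution-matrix scores (BLOSUM62, BLOSUM45 or a PET91-style matrix),
# and the same matrix scores with Henikoff position-based sequence weights.
# Gaps are excluded from frequencies; the gap fraction is reported and
# majority-gap columns are flagged.

#' Consensus reduced-alphabet classes
#'
#' `h` hydrophobic, `u` tiny (A, G, S), `n` acidic (D, E); classes are tried
#' smallest-first so the most specific class wins.  Whether C and Y count as
#' hydrophobic is configurable.
#'
#' @param include_cy include Cys and Tyr in the hydrophobic class (default
#'   TRUE).
#' @export
consensus_alphabet <- function(include_cy = TRUE) {
  h <- c("A", "V", "L", "I", "M", "F", "W")
  if (include_cy) h <- c(h, "C", "Y")
  structure(list(h = h, u = c("A", "G", "S"), n = c("D", "E")),
            class = "consensus_alphabet")
}

#' @noRd
.matrix_cache <- new.env(parent = emptyenv())

#' Retrieve a scoring matrix by name
#'
#' `"BLOSUM62"` and `"BLOSUM45"` come from Biostrings.  `"PET91"` is a
#' PET91-style log-odds matrix derived at load time from the published
#' Jones-Taylor-Thornton (1992) substitution model (exchangeabilities and
#' equilibrium frequencies as shipped by phangorn): the reversible generator
#' is scaled to one expected substitution per site, exponentiated, and
#' converted to half-bit log-odds `round(2 log2 P(a,b|t) / p(b))`.  It is a
#' documented substitute for the modified PET91 matrix whose modification is
#' not publicly specified.
#'
#' @param name matrix name.
#' @return 20 x 20 integer-valued matrix over the amino-acid alphabet.
#' @export
scoring_matrix <- function(name = c("BLOSUM62", "BLOSUM45", "PET91")) {
  name <- match.arg(name)
  if (!is.null(.matrix_cache[[name]])) return(.matrix_cache[[name]])
  m <- if (name %in% c("BLOSUM62", "BLOSUM45")) {
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    full <- e[[name]]
    full[.AA1, .AA1]
  } else {
    pet91_style_matrix()
  }
  .matrix_cache[[name]] <- m
  m
}

#' @noRd
pet91_style_matrix <- function(t = 1) {
  jtt <- get(".JTT", envir = asNamespace("phangorn"))
  pi_ <- as.numeric(jtt$bf)
  S <- matrix(0, 20, 20)
  S[lower.tri(S)] <- jtt$Q
  S <- S + t(S)
  Q <- S %*% diag(pi_)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi_ * diag(Q))
  Q <- Q / mu                       # 1 expected substitution per site
  # reversible generator: symmetrize with sqrt(pi) for a stable exponential
  D <- diag(sqrt(pi_))
  Di <- diag(1 / sqrt(pi_))
  B <- D %*% Q %*% Di
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  P <- Di %*% e$vectors %*% diag(exp(t * e$values)) %*% t(e$vectors) %*% D
  M <- round(2 * log2(sweep(P, 2, pi_, `/`)))
  M <- (M + t(M)) / 2               # numerically symmetric by reversibility
  # phangorn stores frequencies in the PAML amino-acid order
  aa <- toupper(c("a", "r", "n", "d", "c", "q", "e", "g", "h", "i",
                  "l", "k", "m", "f", "p", "s", "t", "w", "y", "v"))
  dimnames(M) <- list(aa, aa)
  M[.AA1, .AA1]
}

#' Henikoff position-based sequence weights
#'
#' @param aln an [alignment_block()].
#' @return numeric weights (one per sequence, summing to 1).
#' @export
henikoff_weights <- function(aln) {
  w <- numeric(length(aln$ids))
  for (cix in seq_len(aln$ncol)) {
    col <- aln$mat[, cix]
    ok <- col %in% .AA1
    if (!any(ok)) next
    tab <- table(col[ok])
    r <- length(tab)
    contrib <- 1 / (r * as.numeric(tab[col[ok]]))
    w[ok] <- w[ok] + contrib
  }
  if (sum(w) == 0) w <- rep(1, length(w))
  w / sum(w)
}

#' Score alignment columns for conservation
#'
#' Entropy is `-sum p log2 p` over observed residues (0 for an invariant
#' column, log2 20 for a uniform one); matrix scores are the mean pairwise
#' substitution score over unordered sequence pairs, normalized to [0, 1] by
#' the matrix minimum/maximum; the weighted variant replaces the plain mean
#' with Henikoff-weighted pairs so duplicated sequences are down-weighted.
#' `average_conservation` is the mean of the requested normalized scores.
#'
#' @param aln an [alignment_block()].
#' @param methods subset of `c("entropy", "matrix", "weighted")`.
#' @param matrix scoring-matrix name (see [scoring_matrix()]).
#' @return data.frame of class `column_scores` with one row per column:
#'   `column`, `gap_fraction`, `gap_flag` (> 50 % gaps), `entropy` (bits),
#'   `entropy_score` (normalized), `matrix_score`, `weighted_score`,
#'   `average_conservation`.
#' @export
score_columns <- function(aln, methods = c("entropy", "matrix", "weighted"),
                          matrix = "BLOSUM62") {
  methods <- match.arg(methods, several.ok = TRUE)
  M <- if (any(c("matrix", "weighted") %in% methods)) scoring_matrix(matrix)
  w_all <- if ("weighted" %in% methods) henikoff_weights(aln)
  nseq <- length(aln$ids)
  out <- data.frame(column = seq_len(aln$ncol))
  out$gap_fraction <- NA_real_
  out$entropy <- NA_real_
  out$entropy_score <- NA_real_
  out$matrix_score <- NA_real_
  out$weighted_score <- NA_real_
  if (!is.null(M)) {
    mmin <- min(M); mmax <- max(M)
  }
  for (cix in seq_len(aln$ncol)) {
    col <- aln$mat[, cix]
    ok <- col %in% .AA1
    out$gap_fraction[cix] <- mean(col == "-")
    if (!any(ok)) next
    aa <- col[ok]
    if ("entropy" %in% methods) {
      p <- table(aa) / length(aa)
      H <- -sum(p * log2(p))
      out$entropy[cix] <- H
      out$entropy_score[cix] <- 1 - H / log2(20)
    }
    if (!is.null(M) && length(aa) >= 2) {
      ij <- utils::combn(which(ok), 2)
      sc <- M[cbind(col[ij[1, ]], col[ij[2, ]])]
      if ("matrix" %in% methods) {
        out$matrix_score[cix] <- (mean(sc) - mmin) / (mmax - mmin)
      }
      if ("weighted" %in% methods) {
        wp <- w_all[ij[1, ]] * w_all[ij[2, ]]
        out$weighted_score[cix] <- (sum(wp * sc) / sum(wp) - mmin) / (mmax - mmin)
      }
    }
  }
  out$gap_flag <- out$gap_fraction > 0.5
  score_cols <- c(entropy = "entropy_score", matrix = "matrix_score",
                  weighted = "weighted_score")[methods]
  out$average_conservation <- rowMeans(out[, score_cols, drop = FALSE],
                                       na.rm = TRUE)
  class(out) <- c("column_scores", "data.frame")
  attr(out, "matrix") <- matrix
  attr(out, "methods") <- methods
  out
}

#' Consensus pattern of an alignment
#'
#' Per column: the literal residue if its frequency (gaps excluded) reaches
#' the threshold; else a paired alternative `(A,B)` if the two most frequent
#' residues jointly reach it; else the smallest reduced-alphabet class
#' (acidic `n` < tiny `u` < hydrophobic `h`) whose members jointly reach it;
#' else `x`.  Majority-gap columns emit `-`.  Raising the threshold can only
#' make a symbol less specific (literal -> pair -> class -> x).
#'
#' @param aln an [alignment_block()].
#' @param threshold conserved-fraction threshold in (0.5, 1] (the reference
#'   analyses use 0.70 and 0.80).
#' @param alphabet a [consensus_alphabet()].
#' @param class_over_pair prefer a qualifying reduced-alphabet class over a
#'   paired alternative whose two residues both belong to it (default FALSE:
#'   the pair is the more specific symbol).
#' @return character vector of per-column symbols, with the collapsed
#'   pattern in attribute `pattern`.
#' @export
consensus_pattern <- function(aln, threshold = 0.70,
                              alphabet = consensus_alphabet(),
                              class_over_pair = FALSE) {
  if (threshold <= 0.5 || threshold > 1) stopf("threshold must be in (0.5, 1]")
  classes <- alphabet[order(lengths(alphabet))]
  syms <- character(aln$ncol)
  for (cix in seq_len(aln$ncol)) {
    col <- aln$mat[, cix]
    if (mean(col == "-") > 0.5) {
      syms[cix] <- "-"
      next
    }
    aa <- col[col %in% .AA1]
    if (length(aa) == 0) {
      syms[cix] <- "x"
      next
    }
    p <- sort(table(aa) / length(aa), decreasing = TRUE)
    class_sym <- function() {
      for (cl in names(classes)) {
        if (sum(p[names(p) %in% classes[[cl]]]) >= threshold) return(cl)
      }
      "x"
    }
    if (p[1] >= threshold) {
      syms[cix] <- names(p)[1]
    } else if (length(p) >= 2 && p[1] + p[2] >= threshold) {
      pair_in_class <- any(vapply(classes, function(m)
        all(names(p)[1:2] %in% m), logical(1)))
      syms[cix] <- if (class_over_pair && pair_in_class) class_sym() else
        sprintf("(%s,%s)", names(p)[1], names(p)[2])
    } else {
      syms[cix] <- class_sym()
    }
  }
  attr(syms, "pattern") <- paste(syms, collapse = "")
  syms
}
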