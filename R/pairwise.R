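# Global pairwise protein alignment with EMBOSS-Needle default semantics:
# BLOSUM62, gap open 10, gap extend 0.5, end gaps free (endweight off).
# Identity/similarity percentages are computed over the full padded
# alignment length, as Needle prints them.

#' Needle-style alignment defaults
#' @format Named constants: substitution matrix name, gap penalties.
#' @export
NEEDLE_DEFAULTS <- list(matrix = "BLOSUM62", gap_open = 10.0, gap_extend = 0.5)

# Canonical reference order used for deterministic tie-breaks.
CANONICAL_FAMILIES <- c("HisN", "Cg0911", "ImpA", "SuhB", "CysQ")

get_submat <- function(matrix) {
  if (is.matrix(matrix)) return(matrix)
  e <- new.env()
  utils::data(list = matrix, package = "Biostrings", envir = e)
  get(matrix, envir = e)
}

#' Global pairwise protein alignment (Needle semantics)
#'
#' Optimal global affine-gap alignment (Needleman-Wunsch/Gotoh) with free
#' end gaps. A gap run of length L costs `gap_open + gap_extend * L`;
#' terminal gap runs cost nothing.
#'
#' @param a,b [aa_seq] records.
#' @param matrix Substitution matrix name (default `"BLOSUM62"`) or a matrix.
#' @param gap_open,gap_extend Affine gap penalties (Needle defaults 10, 0.5).
#' @return An object of class `global_alignment` with fields `gapped_a`,
#'   `gapped_b` (equal-length, padded to cover both inputs fully), `score`,
#'   `identity_pct`, `similarity_pct`, `gaps_pct` (one decimal) and `length`.
#' @details `identity_pct` is the fraction of columns with identical
#'   residues; `similarity_pct` the fraction whose residue pair scores
#'   positively in the substitution matrix (identities included when their
#'   diagonal score is positive, the EMBOSS convention); both relative to
#'   the full alignment length including end gaps.
#' @export
global_align <- function(a, b, matrix = NEEDLE_DEFAULTS$matrix,
                         gap_open = NEEDLE_DEFAULTS$gap_open,
                         gap_extend = NEEDLE_DEFAULTS$gap_extend) {
  stopifnot(inherits(a, "aa_seq"), inherits(b, "aa_seq"))
  submat <- get_submat(matrix)
  for (s in list(a, b)) {
    chars <- unique(strsplit(s$residues, "", fixed = TRUE)[[1L]])
    missing <- setdiff(chars, rownames(submat))
    if (length(missing))
      stop("residue '", missing[1L], "' in sequence '", s$id,
           "' is absent from the substitution matrix")
  }
  p <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a$residues), Biostrings::AAString(b$residues),
    substitutionMatrix = submat, gapOpening = gap_open,
    gapExtension = gap_extend, type = "overlap")

  core_a <- as.character(Biostrings::alignedPattern(p))
  core_b <- as.character(Biostrings::alignedSubject(p))
  sa <- Biostrings::start(Biostrings::pattern(p))
  ea <- Biostrings::end(Biostrings::pattern(p))
  sb <- Biostrings::start(Biostrings::subject(p))
  eb <- Biostrings::end(Biostrings::subject(p))
  na <- nchar(a$residues); nb <- nchar(b$residues)

  # Pad unaligned terminal flanks back in, Needle-style: the skipped prefix
  # (suffix) of each input is stacked against gaps; b's flank first, then
  # a's, so no column is gap-gap.
  pre_b <- if (sb > 1L) substring(b$residues, 1L, sb - 1L) else ""
  pre_a <- if (sa > 1L) substring(a$residues, 1L, sa - 1L) else ""
  suf_b <- if (eb < nb) substring(b$residues, eb + 1L, nb) else ""
  suf_a <- if (ea < na) substring(a$residues, ea + 1L, na) else ""
  gaps <- function(n) strrep("-", n)
  gapped_a <- paste0(gaps(nchar(pre_b)), pre_a, core_a, suf_a, gaps(nchar(suf_b)))
  gapped_b <- paste0(pre_b, gaps(nchar(pre_a)), core_b, gaps(nchar(suf_a)), suf_b)

  ca <- strsplit(gapped_a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(gapped_b, "", fixed = TRUE)[[1L]]
  stopifnot(length(ca) == length(cb))
  len <- length(ca)
  is_gap <- ca == "-" | cb == "-"
  ident <- sum(!is_gap & ca == cb)
  pair_scores <- rep(NA_real_, len)
  if (any(!is_gap))
    pair_scores[!is_gap] <- submat[cbind(ca[!is_gap], cb[!is_gap])]
  simil <- sum(pair_scores > 0, na.rm = TRUE)

  structure(list(
    id_a = a$id, id_b = b$id,
    gapped_a = gapped_a, gapped_b = gapped_b,
    score = unname(Biostrings::score(p)),
    length = len,
    identity_pct = round(100 * ident / len, 1),
    similarity_pct = round(100 * simil / len, 1),
    gaps_pct = round(100 * sum(is_gap) / len, 1)
  ), class = "global_alignment")
}

#' @export
print.global_alignment <- function(x, ...) {
  cat(sprintf("<global_alignment> %s vs %s: length %d, score %.1f\n",
              x$id_a, x$id_b, x$length, x$score))
  cat(sprintf("  identity %.1f%%  similarity %.1f%%  gaps %.1f%%\n",
              x$identity_pct, x$similarity_pct, x$gaps_pct))
  invisible(x)
}

#' Per-reference similarity summary for a query
#'
#' Aligns a query against each reference and reports identity, similarity,
#' gaps and score; the best reference maximizes the alignment score, with a
#' deterministic tie-break in canonical family order (HisN, Cg0911, ImpA,
#' SuhB, CysQ), then input order.
#'
#' @param query An [aa_seq].
#' @param refs A non-empty list of [aa_seq] references (named by id).
#' @return A data.frame with one row per reference (columns `ref_id`,
#'   `identity_pct`, `similarity_pct`, `gaps_pct`, `score`, `length`,
#'   `best`), carrying the best reference id as attribute `"best"`.
#' @export
similarity_profile <- function(query, refs, matrix = NEEDLE_DEFAULTS$matrix,
                               gap_open = NEEDLE_DEFAULTS$gap_open,
                               gap_extend = NEEDLE_DEFAULTS$gap_extend) {
  refs <- as_aa_seq_list(refs)
  if (!length(refs)) stop("refs must be non-empty")
  alns <- lapply(refs, function(r)
    global_align(query, r, matrix, gap_open, gap_extend))
  df <- data.frame(
    ref_id = names(refs),
    identity_pct = vapply(alns, `[[`, numeric(1), "identity_pct"),
    similarity_pct = vapply(alns, `[[`, numeric(1), "similarity_pct"),
    gaps_pct = vapply(alns, `[[`, numeric(1), "gaps_pct"),
    score = vapply(alns, `[[`, numeric(1), "score"),
    length = vapply(alns, `[[`, integer(1), "length"),
    stringsAsFactors = FALSE, row.names = NULL)
  ord <- order(match(df$ref_id, CANONICAL_FAMILIES, nomatch = NA),
               seq_len(nrow(df)))
  best <- df$ref_id[ord][which.max(df$score[ord])]
  df$best <- df$ref_id == best
  attr(df, "best") <- best
  attr(df, "alignments") <- alns
  df
}
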