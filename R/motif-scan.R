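# Mapping reference motif coordinates onto query sequences and evaluating
# motif presence.

#' Map reference positions onto a query via global alignment
#'
#' @param query,reference [aa_seq] records.
#' @return Integer vector of length `nchar(reference)`: the 1-based query
#'   position aligned to each reference position, `NA` where the reference
#'   position is aligned to a gap (deletion in the query). The mapping is
#'   strictly monotone over its defined entries.
#' @export
anchor_map <- function(query, reference, ...) {
  aln <- global_align(reference, query, ...)
  ra <- strsplit(aln$gapped_a, "", fixed = TRUE)[[1L]]
  qa <- strsplit(aln$gapped_b, "", fixed = TRUE)[[1L]]
  map <- integer(0)
  ri <- 0L; qi <- 0L
  out <- rep(NA_integer_, nchar(reference$residues))
  for (i in seq_along(ra)) {
    if (qa[i] != "-") qi <- qi + 1L
    if (ra[i] != "-") {
      ri <- ri + 1L
      out[ri] <- if (qa[i] != "-") qi else NA_integer_
    }
  }
  out
}

# Evaluate one variant (positions + pair rules) of a motif on a query.
# Returns list(required_ok, preferred_frac, outcomes, veto).
eval_variant <- function(positions, pair_rules, map, qchars) {
  res_at <- function(ref_pos) {
    qp <- if (ref_pos <= length(map)) map[ref_pos] else NA_integer_
    if (is.na(qp) || qp > length(qchars)) NA_character_ else qchars[qp]
  }
  n <- length(positions)
  outcomes <- data.frame(
    ref_pos = integer(n), query_pos = integer(n), residue = character(n),
    level = character(n), satisfied = logical(n), stringsAsFactors = FALSE)
  req_ok <- TRUE
  pref_sat <- 0L; pref_tot <- 0L
  for (i in seq_along(positions)) {
    p <- positions[[i]]
    qp <- if (p$ref_pos <= length(map)) map[p$ref_pos] else NA_integer_
    res <- res_at(p$ref_pos)
    sat <- !is.na(res) && (res %in% p$allowed) && !(res %in% p$forbidden)
    outcomes[i, ] <- list(p$ref_pos, ifelse(is.na(qp), NA_integer_, qp),
                          ifelse(is.na(res), "-", res), p$level, sat)
    if (p$level == "required") req_ok <- req_ok && sat
    else { pref_tot <- pref_tot + 1L; pref_sat <- pref_sat + sat }
  }
  veto <- FALSE
  for (r in pair_rules) {
    r1 <- res_at(r$positions[1L]); r2 <- res_at(r$positions[2L])
    if (identical(r$type, "xor_aromatic_small")) {
      arom <- residue_class("aromatic"); small <- residue_class("small")
      a1 <- !is.na(r1) && r1 %in% arom
      a2 <- !is.na(r2) && r2 %in% arom
      req_ok <- req_ok && xor(a1, a2)
      counterpart <- if (a1) r2 else r1
      pref_tot <- pref_tot + 1L
      pref_sat <- pref_sat + (xor(a1, a2) && !is.na(counterpart) &&
                              counterpart %in% small)
    } else if (identical(r$type, "forbidden_pair")) {
      veto <- veto || (identical(r1, r$residues[1L]) &&
                       identical(r2, r$residues[2L]))
    } else stop("unknown pair rule type: ", r$type)
  }
  list(required_ok = req_ok,
       preferred_frac = if (pref_tot) pref_sat / pref_tot else 1,
       outcomes = outcomes, veto = veto)
}

#' Scan a query for the motifs of one family
#'
#' Positions of each motif are mapped from the family's reference onto the
#' query through the optimal global alignment; a motif is present when all
#' required positions of its main or of any alternative variant are
#' satisfied, no forbidden pair fires, and the satisfied fraction of
#' preferred outcomes reaches the motif's threshold.
#'
#' @param query An [aa_seq].
#' @param family Family name present in `rules`.
#' @param rules Rule set as from [builtin_rules] or [read_motif_rules].
#' @param reference The family's reference [aa_seq] (the protein in whose
#'   coordinates the rules are written).
#' @return A list of `motif_hit` objects (class `motif_scan`), one per
#'   motif, each with `family`, `index`, `present`, `variant_used`,
#'   `outcomes` (per-position table), and `extracted_string` (query
#'   residues across the motif's reference span, `-` marking deletions).
#' @export
scan_motifs <- function(query, family, rules = builtin_rules(), reference) {
  if (!family %in% names(rules)) stop("no rules for family '", family, "'")
  defs <- rules[[family]]
  stopifnot(inherits(reference, "aa_seq"))
  map <- tryCatch(anchor_map(query, reference), error = function(e) e)
  qchars <- strsplit(query$residues, "", fixed = TRUE)[[1L]]
  hits <- lapply(defs, function(d) {
    if (inherits(map, "error")) {
      return(structure(list(
        family = d$family, index = d$index, present = FALSE,
        variant_used = NA_character_, outcomes = NULL,
        extracted_string = "",
        diagnostic = paste("anchor failure:", conditionMessage(map))),
        class = "motif_hit"))
    }
    main <- eval_variant(d$positions, d$pair_rules, map, qchars)
    variants <- c(list(main),
                  lapply(d$alternatives, function(a)
                    eval_variant(a$positions, a$pair_rules %||% list(),
                                 map, qchars)))
    ok <- vapply(variants, function(v)
      v$required_ok && !v$veto &&
        v$preferred_frac >= d$preferred_fraction_threshold, logical(1))
    used <- if (any(ok)) which(ok)[1L] else 1L
    span <- range(vapply(d$positions, `[[`, integer(1), "ref_pos"))
    extracted <- paste(vapply(span[1L]:span[2L], function(rp) {
      qp <- if (rp <= length(map)) map[rp] else NA_integer_
      if (is.na(qp)) "-" else qchars[qp]
    }, character(1)), collapse = "")
    structure(list(
      family = d$family, index = d$index, present = any(ok),
      variant_used = if (used == 1L) "main" else paste0("alt", used - 1L),
      outcomes = variants[[used]]$outcomes,
      extracted_string = extracted, diagnostic = NULL),
      class = "motif_hit")
  })
  structure(hits, class = "motif_scan", query_id = query$id, family = family)
}

#' @export
print.motif_scan <- function(x, ...) {
  cat(sprintf("<motif_scan> query %s vs %s rules\n",
              attr(x, "query_id"), attr(x, "family")))
  for (h in x)
    cat(sprintf("  motif %d: %-7s %s  %s\n", h$index,
                if (h$present) "present" else "absent",
                if (is.na(h$variant_used)) "" else paste0("(", h$variant_used, ")"),
                h$extracted_string))
  invisible(x)
}

#' Summarize motif presence as a logical vector
#' @param scan A `motif_scan` from [scan_motifs].
#' @return Named logical vector indexed by motif index.
#' @export
motif_presence <- function(scan) {
  stats::setNames(vapply(scan, `[[`, logical(1), "present"),
                  vapply(scan, `[[`, integer(1), "index"))
}

#' Per-column conservation profile of an alignment
#'
#' @param msa An [aa_msa] with at least 2 rows.
#' @return A `conservation_profile`: list with `frequencies` (a
#'   (residues+gap) x columns matrix, each column summing to 1), `category`
#'   (per column: `strict` when the most frequent residue reaches 0.98,
#'   `high` at 0.90, `moderate` at 0.50, else `variable`; gaps count in the
#'   denominator but not as the consensus residue) and `n_sequences`.
#' @export
conservation_profile <- function(msa) {
  stopifnot(inherits(msa, "aa_msa"))
  chars <- do.call(rbind, strsplit(unname(msa$rows), "", fixed = TRUE))
  syms <- c(AA_ALPHABET_X, "-")
  freq <- apply(chars, 2, function(col) {
    tab <- table(factor(col, levels = syms))
    as.numeric(tab) / length(col)
  })
  rownames(freq) <- syms
  maxres <- apply(freq[AA_ALPHABET_X, , drop = FALSE], 2, max)
  category <- cut(maxres, breaks = c(-Inf, 0.5, 0.9, 0.98, Inf),
                  labels = c("variable", "moderate", "high", "strict"),
                  right = FALSE)
  structure(list(frequencies = freq, category = as.character(category),
                 max_residue_freq = maxres, n_sequences = length(msa$ids)),
            class = "conservation_profile")
}
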