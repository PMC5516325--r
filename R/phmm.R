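# Profile hidden Markov models: construction from an alignment, forward /
# Viterbi scoring in log space, Gumbel E-value calibration, and
# jackhmmer-style iterative search.
#
# Architecture: Plan7-like match/insert/delete nodes without the flanking
# N/C/J loop states. The model is matched globally; the sequence is matched
# locally in the sense that leading and trailing residues are absorbed by
# the terminal insert states I0 / IM, whose emissions equal the background
# (zero log-odds), so flanking sequence costs only transition probability.

# Default inclusion threshold used for UniProt-scale searches.
PAPER_INCLUSION_EVALUE <- 1e-65

aa_codes <- function(residues) {
  chars <- strsplit(residues, "", fixed = TRUE)[[1L]]
  codes <- match(chars, AA_STANDARD) - 1L
  codes[chars == "X"] <- 20L
  if (anyNA(codes)) stop("residue outside the amino-acid alphabet")
  codes
}

#' Build a profile HMM from a multiple alignment
#'
#' Match states are the alignment columns with gap fraction below 0.5.
#' Match emissions are per-column residue counts plus a background-weighted
#' pseudocount, normalized; insert emissions equal the background;
#' transitions are estimated from the observed per-row state paths with
#' Laplace (+1) smoothing. Construction is deterministic.
#'
#' @param msa An [aa_msa] (at least 2 rows).
#' @param pseudocount_weight Total pseudocount mass added to each match
#'   column (spread as `weight * background`), default 0.1.
#' @param background Background residue frequencies (default BLOSUM62
#'   marginals).
#' @param name Model name recorded in the metadata.
#' @return A `profile_hmm` with fields `M`, `match_emission` (M x 20),
#'   `insert_emission` ((M+1) x 20), `transitions`, `background`,
#'   `column_map` and `metadata` (including the UniProt-scale default
#'   inclusion E-value of 1e-65).
#' @export
build_hmm <- function(msa, pseudocount_weight = 0.1, background = BG_FREQS,
                      name = "impscan_model") {
  stopifnot(inherits(msa, "aa_msa"))
  chars <- do.call(rbind, strsplit(unname(msa$rows), "", fixed = TRUE))
  gapfrac <- colMeans(chars == "-")
  match_cols <- which(gapfrac < 0.5)
  M <- length(match_cols)
  if (M == 0L) stop("alignment has no match columns (all gap fraction >= 0.5)")
  background <- background[AA_STANDARD] / sum(background[AA_STANDARD])

  match_emission <- t(vapply(match_cols, function(j) {
    counts <- table(factor(chars[, j], levels = AA_STANDARD))
    p <- as.numeric(counts) + pseudocount_weight * background
    p / sum(p)
  }, numeric(20)))
  colnames(match_emission) <- AA_STANDARD
  insert_emission <- matrix(background, nrow = M + 1L, ncol = 20L,
                            byrow = TRUE, dimnames = list(NULL, AA_STANDARD))

  # Transition counts from observed state paths. Node index k = 0..M;
  # vector slot k+1. Disallowed I<->D transitions in raw paths are skipped.
  zero <- rep(0, M + 1L)
  cnt <- list(MM = zero, MI = zero, MD = zero, IM = zero, II = zero,
              DM = zero, DD = zero)
  is_match <- logical(ncol(chars)); is_match[match_cols] <- TRUE
  node_of_col <- cumsum(is_match)
  for (r in seq_len(nrow(chars))) {
    state <- "M"; node <- 0L
    advance <- function(new_state, new_node) {
      key <- paste0(state, new_state)
      if (!is.null(cnt[[key]]))
        cnt[[key]][node + 1L] <<- cnt[[key]][node + 1L] + 1
      state <<- new_state; node <<- new_node
    }
    for (j in seq_len(ncol(chars))) {
      res <- chars[r, j] != "-"
      if (is_match[j]) advance(if (res) "M" else "D", node_of_col[j])
      else if (res) advance("I", node)
    }
    advance("M", M + 1L) # to end state, counted as M/I/D -> E
  }

  lap <- function(x) x + 1
  tMM <- tMI <- tMD <- tIM <- tII <- tDM <- tDD <- rep(-Inf, M + 1L)
  for (k in 0:M) {
    i <- k + 1L
    if (k < M) {
      m <- lap(c(cnt$MM[i], cnt$MI[i], cnt$MD[i])); m <- m / sum(m)
      tMM[i] <- log(m[1]); tMI[i] <- log(m[2]); tMD[i] <- log(m[3])
    } else {
      m <- lap(c(cnt$MM[i], cnt$MI[i])); m <- m / sum(m)
      tMM[i] <- log(m[1]); tMI[i] <- log(m[2]) # tMD[M] stays -Inf
    }
    ii <- lap(c(cnt$IM[i], cnt$II[i])); ii <- ii / sum(ii)
    tIM[i] <- log(ii[1]); tII[i] <- log(ii[2])
    if (k >= 1) {
      if (k < M) {
        d <- lap(c(cnt$DM[i], cnt$DD[i])); d <- d / sum(d)
        tDM[i] <- log(d[1]); tDD[i] <- log(d[2])
      } else {
        tDM[i] <- 0 # D_M -> E with probability 1
      }
    }
  }

  structure(list(
    M = M,
    match_emission = match_emission,
    insert_emission = insert_emission,
    transitions = list(MM = tMM, MI = tMI, MD = tMD, IM = tIM, II = tII,
                       DM = tDM, DD = tDD),
    background = background,
    column_map = match_cols,
    metadata = list(name = name, n_seqs = length(msa$ids),
                    pseudocount_weight = pseudocount_weight,
                    inclusion_evalue = PAPER_INCLUSION_EVALUE),
    calibration = NULL
  ), class = "profile_hmm")
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("<profile_hmm> %s: M = %d match states, built from %d sequences%s\n",
              x$metadata$name, x$M, x$metadata$n_seqs,
              if (is.null(x$calibration)) "" else " (calibrated)"))
  invisible(x)
}

model_log_params <- function(model) {
  list(lmatch = log(model$match_emission),
       linsert = log(model$insert_emission),
       t = model$transitions)
}

#' Score a sequence against a profile HMM
#'
#' Forward (sum over paths) or Viterbi (best path) scoring in log space.
#' The bit score is the log2-odds of the sequence under the model versus an
#' i.i.d. background null; residues coded `X` contribute zero log-odds.
#'
#' @param model A `profile_hmm`.
#' @param seq An [aa_seq].
#' @param mode `"forward"` or `"viterbi"`.
#' @return List with `bit_score`, `log_prob` (natural-log sequence
#'   probability under the model), `log_null`, and for Viterbi a `path`
#'   data.frame (`state` in M/I/D, `node`, `seq_pos`).
#' @export
phmm_score <- function(model, seq, mode = c("forward", "viterbi")) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "profile_hmm"), inherits(seq, "aa_seq"))
  codes <- aa_codes(seq$residues)
  p <- model_log_params(model)
  lbg <- log(model$background)
  log_null <- sum(ifelse(codes >= 20L, 0, lbg[codes + 1L]))
  if (mode == "forward") {
    lp <- .phmm_forward(codes, p$lmatch, p$linsert, p$t$MM, p$t$MI, p$t$MD,
                        p$t$IM, p$t$II, p$t$DM, p$t$DD)
    path <- NULL
  } else {
    v <- .phmm_viterbi(codes, p$lmatch, p$linsert, p$t$MM, p$t$MI, p$t$MD,
                       p$t$IM, p$t$II, p$t$DM, p$t$DD)
    lp <- v$logp
    path <- data.frame(state = c("M", "I", "D")[v$state + 1L],
                       node = v$node, seq_pos = v$seq_pos,
                       stringsAsFactors = FALSE)
  }
  list(bit_score = (lp - log_null) / log(2), log_prob = lp,
       log_null = log_null, mode = mode, path = path)
}

#' Calibrate the E-value tail of a model
#'
#' Scores `n` random background sequences of the stated length with the
#' forward algorithm and fits a Gumbel (type-I extreme value) distribution
#' to the bit scores by maximum likelihood.
#'
#' @param model A `profile_hmm`.
#' @param length Length of the calibration sequences (default: the model's
#'   match-state count).
#' @param n Number of random sequences (>= 100; default 1000).
#' @param seed Integer seed.
#' @return The model with a `calibration` element (`mu`, `beta`, `n`,
#'   `length`, `seed`).
#' @export
calibrate_evalues <- function(model, length = NULL, n = 1000L,
                              seed = DEFAULT_SEED) {
  stopifnot(inherits(model, "profile_hmm"), n >= 100L)
  if (is.null(length)) length <- model$M
  scores <- withr_seed(seed, {
    vapply(seq_len(n), function(i) {
      s <- paste(sample(AA_STANDARD, length, replace = TRUE,
                        prob = model$background), collapse = "")
      phmm_score(model, aa_seq(sprintf("rand%d", i), s), "forward")$bit_score
    }, numeric(1))
  })
  beta0 <- stats::sd(scores) * sqrt(6) / pi
  mu0 <- mean(scores) - 0.5772156649 * beta0
  nll <- function(par) {
    mu <- par[1]; beta <- exp(par[2])
    z <- (scores - mu) / beta
    sum(log(beta) + z + exp(-z))
  }
  fit <- stats::optim(c(mu0, log(beta0)), nll, method = "Nelder-Mead")
  model$calibration <- list(mu = fit$par[1], beta = exp(fit$par[2]),
                            n = n, length = length, seed = seed)
  model
}

#' E-value of a bit score
#'
#' Expected number of random database sequences scoring at least as high,
#' under the calibrated Gumbel tail: `db_size * P(S >= s)`.
#'
#' @param model A calibrated `profile_hmm` (see [calibrate_evalues]).
#' @param bit_score Bit score(s).
#' @param db_size Number of sequences in the searched database.
#' @return E-value(s), linear in `db_size` and strictly decreasing in the
#'   bit score.
#' @export
estimate_evalue <- function(model, bit_score, db_size) {
  if (is.null(model$calibration))
    stop("model is not calibrated; run calibrate_evalues() first")
  z <- (bit_score - model$calibration$mu) / model$calibration$beta
  p <- -expm1(-exp(-z)) # P(S >= s), upper Gumbel tail
  pmax(db_size * p, .Machine$double.xmin)
}

# Align a sequence to the model's match states via Viterbi; returns a
# gapped row of length M (deletions '-'); insert-state residues dropped.
align_to_model <- function(model, seq) {
  sc <- phmm_score(model, seq, "viterbi")
  chars <- strsplit(seq$residues, "", fixed = TRUE)[[1L]]
  row <- rep("-", model$M)
  keep <- sc$path$state == "M"
  row[sc$path$node[keep]] <- chars[sc$path$seq_pos[keep]]
  paste(row, collapse = "")
}

#' Iterative profile-HMM search
#'
#' jackhmmer-style iteration: build a model from the current alignment,
#' score every database sequence (forward), include hits with E-value at or
#' below the inclusion threshold, realign the included hits to the model by
#' Viterbi, rebuild, and repeat until the included set stops changing or
#' `max_iter` is reached.
#'
#' @param seed_input Seed [aa_msa], or a single [aa_seq] (modelled as a
#'   one-sequence alignment).
#' @param db List of [aa_seq] database sequences.
#' @param inclusion_evalue Sequence-level inclusion E-value threshold;
#'   default the UniProt-scale 1e-65 (pass a laxer value for small
#'   databases).
#' @param max_iter Maximum number of iterations.
#' @param pseudocount_weight Passed to [build_hmm].
#' @param calib_n,calib_seed Gumbel calibration controls (see
#'   [calibrate_evalues]).
#' @return An `iterative_search_result`: `included` (list of per-iteration
#'   id sets), `hits` (data.frame of final-iteration `seq_id`, `bit_score`,
#'   `evalue`, `included`), `model` (final calibrated `profile_hmm`),
#'   `converged`, `n_iterations`.
#' @export
iterative_search <- function(seed_input, db,
                             inclusion_evalue = PAPER_INCLUSION_EVALUE,
                             max_iter = 10L, pseudocount_weight = 0.1,
                             calib_n = 1000L, calib_seed = DEFAULT_SEED) {
  db <- as_aa_seq_list(db)
  if (!length(db)) stop("database is empty")
  msa <- if (inherits(seed_input, "aa_msa")) seed_input
         else if (inherits(seed_input, "aa_seq"))
           aa_msa(stats::setNames(rep(seq_residues(seed_input), 2L),
                                  c(seed_input$id, paste0(seed_input$id, "_dup"))))
         else stop("seed must be an aa_msa or aa_seq")
  calib_len <- as.integer(stats::median(vapply(db, length, integer(1))))
  included_sets <- list()
  converged <- FALSE
  hits_df <- NULL
  model <- NULL
  for (iter in seq_len(max_iter)) {
    model <- build_hmm(msa, pseudocount_weight,
                       name = sprintf("iter%d", iter))
    model <- calibrate_evalues(model, length = calib_len, n = calib_n,
                               seed = calib_seed)
    bits <- vapply(db, function(s) phmm_score(model, s, "forward")$bit_score,
                   numeric(1))
    ev <- estimate_evalue(model, bits, db_size = length(db))
    inc <- ev <= inclusion_evalue
    hits_df <- data.frame(seq_id = names(db), bit_score = bits, evalue = ev,
                          included = inc, row.names = NULL,
                          stringsAsFactors = FALSE)
    included_sets[[iter]] <- sort(names(db)[inc])
    if (!any(inc)) {
      warning("no database sequence reached the inclusion threshold")
      converged <- TRUE
      break
    }
    if (iter > 1L &&
        identical(included_sets[[iter]], included_sets[[iter - 1L]])) {
      converged <- TRUE
      break
    }
    rows <- vapply(db[inc], function(s) align_to_model(model, s),
                   character(1))
    if (length(rows) == 1L) {
      rows <- rep(rows, 2L)
      names(rows)[2L] <- paste0(names(rows)[1L], "_dup")
    }
    msa <- aa_msa(rows)
  }
  structure(list(included = included_sets, hits = hits_df, model = model,
                 converged = converged, n_iterations = length(included_sets)),
            class = "iterative_search_result")
}

seq_residues <- function(s) s$residues

#' @export
print.iterative_search_result <- function(x, ...) {
  cat(sprintf("<iterative_search_result> %d iteration(s), %sconverged; %d included\n",
              x$n_iterations, if (x$converged) "" else "NOT ",
              length(x$included[[x$n_iterations]])))
  invisible(x)
}
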