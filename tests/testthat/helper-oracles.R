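# Independent oracles and shared fixtures, built in code at test time.

# Shared rule set and synthetic family references (expensive enough to cache).
RULES <- builtin_rules()
REFS <- local({
  refs <- lapply(names(RULES), make_family_reference)
  names(refs) <- names(RULES)
  for (i in seq_along(refs)) refs[[i]]$id <- names(refs)[i]
  refs
})
SUBMAT <- impscan:::get_submat("BLOSUM62")

random_protein <- function(n, seed) {
  impscan:::withr_seed(seed, paste(
    sample(impscan:::AA_STANDARD, n, replace = TRUE), collapse = ""))
}

# --- Exhaustive global-alignment oracle ------------------------------------
# Enumerates every monotone alignment of a and b (columns: substitution,
# gap-in-a, gap-in-b; no gap-gap columns) and scores it with affine gap
# runs costing open + extend * len, terminal runs free. Returns the optimal
# score. Exponential: only for short sequences.
brute_align_score <- function(a, b, gap_open = 10, gap_extend = 0.5,
                              submat = SUBMAT) {
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  na <- length(ca); nb <- length(cb)
  ops <- integer(na + nb) # 1 = sub, 2 = gap in a (consumes b), 3 = gap in b
  best <- -Inf
  score_leaf <- function(depth) {
    s <- 0
    i <- 0L; j <- 0L
    run_type <- 0L; run_len <- 0L; run_start <- 0L
    flush <- function(run_type, run_len, run_start, end_col) {
      if (run_len == 0L) return(0)
      terminal <- run_start == 1L || end_col > depth
      if (terminal) 0 else -(gap_open + gap_extend * run_len)
    }
    k <- 1L
    while (k <= depth) {
      op <- ops[k]
      if (op == 1L) {
        if (run_len > 0L) {
          s <- s + flush(run_type, run_len, run_start, k)
          run_len <- 0L
        }
        i <- i + 1L; j <- j + 1L
        s <- s + submat[ca[i], cb[j]]
      } else {
        if (run_len > 0L && run_type != op) {
          s <- s + flush(run_type, run_len, run_start, k)
          run_len <- 0L
        }
        if (run_len == 0L) run_start <- k
        run_type <- op; run_len <- run_len + 1L
        if (op == 2L) j <- j + 1L else i <- i + 1L
      }
      k <- k + 1L
    }
    if (run_len > 0L) s <- s + flush(run_type, run_len, run_start, depth + 1L)
    s
  }
  rec <- function(i, j, depth) {
    if (i == na && j == nb) {
      s <- score_leaf(depth)
      if (s > best) best <<- s
      return(invisible())
    }
    if (i < na && j < nb) { ops[depth + 1L] <<- 1L; rec(i + 1L, j + 1L, depth + 1L) }
    if (j < nb) { ops[depth + 1L] <<- 2L; rec(i, j + 1L, depth + 1L) }
    if (i < na) { ops[depth + 1L] <<- 3L; rec(i + 1L, j, depth + 1L) }
  }
  rec(0L, 0L, 0L)
  best
}

# --- Profile-HMM forward oracle --------------------------------------------
# Sums sequence probability over every explicit state path through the
# model by depth-first enumeration; independent of the dynamic-programming
# recursions in the package.
brute_forward_logp <- function(model, residues) {
  codes <- match(strsplit(residues, "", fixed = TRUE)[[1L]],
                 impscan:::AA_STANDARD)
  t <- model$transitions; M <- model$M; L <- length(codes)
  em_m <- model$match_emission; em_i <- model$insert_emission
  total <- 0
  rec <- function(type, k, i, logp) {
    if (is.infinite(logp)) return(invisible())
    if (k == M && i == L) {
      te <- switch(type, M = t$MM[M + 1L], I = t$IM[M + 1L], D = t$DM[M + 1L])
      if (is.finite(te)) total <<- total + exp(logp + te)
    }
    tr <- switch(type,
      M = list(c("M", t$MM[k + 1L]), c("I", t$MI[k + 1L]), c("D", t$MD[k + 1L])),
      I = list(c("M", t$IM[k + 1L]), c("I", t$II[k + 1L])),
      D = list(c("M", t$DM[k + 1L]), c("D", t$DD[k + 1L])))
    for (x in tr) {
      nt <- x[1L]; lt <- as.numeric(x[2L])
      if (is.infinite(lt)) next
      if (nt == "M" && k < M && i < L)
        rec("M", k + 1L, i + 1L, logp + lt + log(em_m[k + 1L, codes[i + 1L]]))
      if (nt == "I" && i < L)
        rec("I", k, i + 1L, logp + lt + log(em_i[k + 1L, codes[i + 1L]]))
      if (nt == "D" && k < M)
        rec("D", k + 1L, i, logp + lt)
    }
  }
  rec("M", 0L, 0L, 0)
  as.numeric(log(total))
}

# --- Hill-fit grid oracle ---------------------------------------------------
# Dense (s50, h) grid with the conditionally optimal vmax in closed form,
# polished by Nelder-Mead on all three parameters; returns the residual sum
# of squares.
grid_hill_rss <- function(rates) {
  rss_of <- function(par) {
    v <- impscan:::hill_model(rates$conc, par[1L], par[2L], par[3L])
    sum((rates$rate - v)^2)
  }
  best <- c(Inf, NA, NA, NA)
  s50_grid <- exp(seq(log(min(rates$conc[rates$conc > 0]) / 2),
                      log(max(rates$conc) * 2), length.out = 60L))
  h_grid <- seq(0.3, 5, length.out = 40L)
  for (s50 in s50_grid) for (h in h_grid) {
    g <- rates$conc^h / (s50^h + rates$conc^h)
    vmax <- sum(g * rates$rate) / sum(g^2)
    rss <- sum((rates$rate - vmax * g)^2)
    if (rss < best[1L]) best <- c(rss, vmax, s50, h)
  }
  pol <- stats::optim(best[2:4], rss_of, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  pol$value
}

# Closed-form OLS slope/intercept via the normal equations.
ols_line <- function(x, y) {
  n <- length(x)
  slope <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
  intercept <- mean(y) - slope * mean(x)
  c(intercept = intercept, slope = slope)
}
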