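# Plain-text model serialization mirroring the HMMER3 ASCII layout:
# header keys (NAME, LENG, ALPH), an HMM block with per-node match-emission,
# insert-emission and transition lines holding negative natural-log
# probabilities ('*' = probability zero), terminated by '//'. The reader
# also tolerates genuine HMMER3 files for emission comparison (extra header
# keys and per-line annotation fields are ignored).

HMMER_AA_ORDER <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

fmt_nlp <- function(p) ifelse(p <= 0, "*", sprintf("%.5f", -log(p)))
parse_nlp <- function(tok) {
  out <- numeric(length(tok))
  star <- tok == "*"
  out[!star] <- exp(-as.numeric(tok[!star]))
  out
}

#' Write a profile HMM to a text file
#' @param model A `profile_hmm`.
#' @param path Output path.
#' @export
write_hmm <- function(model, path) {
  stopifnot(inherits(model, "profile_hmm"))
  con <- file(path, "w")
  on.exit(close(con))
  t <- model$transitions
  writeLines(c("HMMER3/f [impscan profile HMM]",
               paste("NAME ", model$metadata$name),
               paste("LENG ", model$M),
               "ALPH  amino",
               paste0("HMM          ", paste(HMMER_AA_ORDER, collapse = "      ")),
               "            m->m   m->i   m->d   i->m   i->i   d->m   d->d"),
             con)
  ins_line <- function(k) paste(" ",
    paste(fmt_nlp(model$insert_emission[k + 1L, HMMER_AA_ORDER]),
          collapse = " "))
  trans_line <- function(k) paste(" ",
    paste(fmt_nlp(exp(c(t$MM[k + 1L], t$MI[k + 1L], t$MD[k + 1L],
                        t$IM[k + 1L], t$II[k + 1L], t$DM[k + 1L],
                        t$DD[k + 1L]))), collapse = " "))
  # Node 0: begin transitions and I0 emissions.
  writeLines(ins_line(0L), con)
  writeLines(trans_line(0L), con)
  for (k in seq_len(model$M)) {
    writeLines(paste(sprintf("%7d", k),
      paste(fmt_nlp(model$match_emission[k, HMMER_AA_ORDER]),
            collapse = " ")), con)
    writeLines(ins_line(k), con)
    writeLines(trans_line(k), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Read a profile HMM from a text file
#'
#' @param path A file written by [write_hmm], or a genuine HMMER3 ASCII
#'   model (match/insert emissions and transitions are recovered; HMMER's
#'   extra annotation fields are skipped).
#' @return A `profile_hmm` (uncalibrated).
#' @export
read_hmm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  name <- "model"; M <- NA_integer_
  i <- 1L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (startsWith(ln, "NAME")) name <- strsplit(ln, "\\s+")[[1L]][2L]
    if (startsWith(ln, "LENG")) M <- as.integer(strsplit(ln, "\\s+")[[1L]][2L])
    if (startsWith(ln, "HMM ") || ln == "HMM") break
    i <- i + 1L
  }
  if (is.na(M)) stop("no LENG header in HMM file: ", path)
  i <- i + 2L # skip the HMM alphabet line and the transition-order line
  # Optional HMMER COMPO line.
  if (startsWith(trimws(lines[i]), "COMPO")) i <- i + 1L
  toks <- function(ln) strsplit(trimws(ln), "\\s+")[[1L]]
  ins0 <- parse_nlp(toks(lines[i])[1:20]); i <- i + 1L
  tr0 <- parse_nlp(toks(lines[i])[1:7]); i <- i + 1L
  match_emission <- matrix(0, M, 20, dimnames = list(NULL, AA_STANDARD))
  insert_emission <- matrix(0, M + 1L, 20, dimnames = list(NULL, AA_STANDARD))
  insert_emission[1L, HMMER_AA_ORDER] <- ins0
  trans <- matrix(0, M + 1L, 7)
  trans[1L, ] <- tr0
  for (k in seq_len(M)) {
    tk <- toks(lines[i]); i <- i + 1L
    if (as.integer(tk[1L]) != k) stop("unexpected node index in HMM file")
    match_emission[k, HMMER_AA_ORDER] <- parse_nlp(tk[2:21])
    insert_emission[k + 1L, HMMER_AA_ORDER] <- parse_nlp(toks(lines[i])[1:20])
    i <- i + 1L
    trans[k + 1L, ] <- parse_nlp(toks(lines[i])[1:7])
    i <- i + 1L
  }
  lg <- function(col) log(trans[, col])
  structure(list(
    M = M,
    match_emission = match_emission,
    insert_emission = insert_emission,
    transitions = list(MM = lg(1), MI = lg(2), MD = lg(3), IM = lg(4),
                       II = lg(5), DM = lg(6), DD = lg(7)),
    background = BG_FREQS,
    column_map = seq_len(M),
    metadata = list(name = name, n_seqs = NA_integer_,
                    pseudocount_weight = NA_real_,
                    inclusion_evalue = PAPER_INCLUSION_EVALUE),
    calibration = NULL
  ), class = "profile_hmm")
}
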