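# Sequence containers, FASTA / alignment I/O, protein mass utilities.

# Residue alphabet: the 20 standard amino acids plus X (unknown).
# B/Z/U and other extended codes are rejected loudly rather than coerced.
AA_STANDARD <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AA_ALPHABET_X <- c(AA_STANDARD, "X")

# Average (not monoisotopic) residue masses in g/mol, IUPAC standard atomic
# weights; a residue mass is the free amino acid minus one water.
AA_RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.01528

#' Create a protein sequence record
#'
#' A sequence record couples a short unique identifier with an uppercase
#' residue string over the 20 standard amino-acid one-letter codes plus `X`.
#'
#' @param id Non-empty identifier string.
#' @param residues Residue string; lowercase input is uppercased.
#' @param description Optional free-text description.
#' @return An object of class `aa_seq` with elements `id`, `description`
#'   and `residues`.
#' @examples
#' aa_seq("a", "MKV")
#' @export
aa_seq <- function(id, residues, description = "") {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("sequence id must be a non-empty string")
  residues <- toupper(as.character(residues))
  if (length(residues) != 1L || !nzchar(residues))
    stop("residues must be a non-empty string (id '", id, "')")
  check_residues(residues, id = id)
  structure(list(id = id, description = as.character(description),
                 residues = residues),
            class = "aa_seq")
}

#' @export
print.aa_seq <- function(x, ...) {
  cat(sprintf("<aa_seq> %s (%d aa)%s\n", x$id, nchar(x$residues),
              if (nzchar(x$description)) paste0(" ", x$description) else ""))
  invisible(x)
}

#' @export
length.aa_seq <- function(x) nchar(x$residues)

# Validate a residue string; errors name the first offending position.
check_residues <- function(residues, id = "?", allow_gap = FALSE) {
  chars <- strsplit(residues, "", fixed = TRUE)[[1L]]
  ok <- AA_ALPHABET_X
  if (allow_gap) ok <- c(ok, "-")
  bad <- which(!(chars %in% ok))
  if (length(bad)) {
    stop(sprintf(
      "invalid residue '%s' at position %d in sequence '%s' (allowed: 20 standard amino acids + X%s)",
      chars[bad[1L]], bad[1L], id, if (allow_gap) " and '-'" else ""))
  }
  invisible(TRUE)
}

as_aa_seq_list <- function(x) {
  if (inherits(x, "aa_seq")) x <- list(x)
  stopifnot(all(vapply(x, inherits, logical(1), "aa_seq")))
  if (is.null(names(x)) || any(!nzchar(names(x))))
    names(x) <- vapply(x, `[[`, character(1), "id")
  x
}

#' Read protein sequences from a FASTA file
#'
#' @param path Path to a FASTA text file.
#' @return A named list of [aa_seq] records, in file order.
#' @details Wrapped sequence lines are concatenated and uppercased.
#'   An empty file, duplicated identifiers, or residues outside the
#'   20-amino-acid + X alphabet raise errors.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no records in FASTA file: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate sequence id in FASTA: '", dup[1L], "'")
  recs <- lapply(seq_along(set), function(i) {
    aa_seq(ids[i], as.character(set[[i]]), desc[i])
  })
  as_aa_seq_list(recs)
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs A list of [aa_seq] records (or a single record).
#' @param path Output path.
#' @param width Line wrap width, default 60 columns.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  seqs <- as_aa_seq_list(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in seqs) {
    header <- if (nzchar(s$description)) paste(s$id, s$description) else s$id
    writeLines(paste0(">", header), con)
    n <- nchar(s$residues)
    starts <- seq(1L, n, by = width)
    writeLines(substring(s$residues, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' Construct a multiple protein alignment
#'
#' @param rows Named character vector of equal-length gapped residue strings
#'   (gap character `-`; `.` is normalized to `-`, case to upper).
#' @return An object of class `aa_msa` with elements `ids`, `rows` and
#'   `n_columns`.
#' @export
aa_msa <- function(rows) {
  if (is.list(rows)) rows <- unlist(rows)
  if (is.null(names(rows)) || any(!nzchar(names(rows))))
    stop("alignment rows must be named by sequence id")
  if (length(rows) < 2L) stop("an alignment needs at least 2 rows")
  rows <- toupper(gsub(".", "-", rows, fixed = TRUE))
  lens <- nchar(rows)
  if (length(unique(lens)) != 1L) {
    bad <- names(rows)[lens != lens[1L]][1L]
    stop("ragged alignment: row '", bad, "' has a different length")
  }
  for (i in seq_along(rows)) {
    check_residues(rows[[i]], id = names(rows)[i], allow_gap = TRUE)
    if (!nzchar(gsub("-", "", rows[[i]], fixed = TRUE)))
      stop("row '", names(rows)[i], "' is all gaps")
  }
  structure(list(ids = names(rows), rows = rows,
                 n_columns = unname(lens[1L])),
            class = "aa_msa")
}

#' @export
print.aa_msa <- function(x, ...) {
  cat(sprintf("<aa_msa> %d sequences x %d columns\n",
              length(x$ids), x$n_columns))
  invisible(x)
}

#' Read a multiple alignment
#'
#' @param path Input file.
#' @param dialect One of `"afa"` (aligned FASTA), `"stockholm"`, `"clustal"`.
#' @return An [aa_msa].
#' @details `#=GC`/`#=GS` and other Stockholm annotation lines are ignored;
#'   `.` gaps are normalized to `-` and case to upper in all dialects, so the
#'   three encodings of one alignment parse identically.
#' @export
read_alignment <- function(path, dialect = c("afa", "stockholm", "clustal")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  rows <- switch(dialect,
    afa = {
      set <- Biostrings::readBStringSet(path)
      if (length(set) == 0L) stop("no records in alignment file: ", path)
      stats::setNames(as.character(set), sub("\\s.*$", "", names(set)))
    },
    stockholm = read_stockholm_rows(path),
    clustal = read_clustal_rows(path)
  )
  aa_msa(rows)
}

# Stockholm: id <seq> data lines, possibly in several blocks; '#' lines are
# annotations, '//' terminates. No installed R package parses Stockholm.
read_stockholm_rows <- function(path) {
  lines <- readLines(path, warn = FALSE)
  acc <- list()
  order <- character(0)
  for (ln in lines) {
    if (grepl("^\\s*$", ln) || startsWith(ln, "#") || startsWith(ln, "//"))
      next
    parts <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(parts) != 2L)
      stop("malformed Stockholm sequence line: ", ln)
    id <- parts[1L]
    if (is.null(acc[[id]])) {
      acc[[id]] <- parts[2L]
      order <- c(order, id)
    } else {
      acc[[id]] <- paste0(acc[[id]], parts[2L])
    }
  }
  if (!length(acc)) stop("no sequence rows in Stockholm file: ", path)
  stats::setNames(unlist(acc[order]), order)
}

# Clustal: a header line, then blocks of "name  segment" lines; the
# conservation line (leading whitespace) and blank lines are skipped.
read_clustal_rows <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^CLUSTAL", lines[1L]))
    stop("not a Clustal file (missing CLUSTAL header): ", path)
  acc <- list()
  order <- character(0)
  for (ln in lines[-1L]) {
    if (grepl("^\\s*$", ln) || grepl("^\\s", ln)) next # conservation line
    parts <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(parts) < 2L) next
    id <- parts[1L]
    seg <- gsub("[0-9]", "", parts[2L]) # tolerate residue counters
    if (is.null(acc[[id]])) {
      acc[[id]] <- seg
      order <- c(order, id)
    } else {
      acc[[id]] <- paste0(acc[[id]], seg)
    }
  }
  if (!length(acc)) stop("no sequence rows in Clustal file: ", path)
  stats::setNames(unlist(acc[order]), order)
}

#' Write a multiple alignment
#'
#' @param msa An [aa_msa].
#' @param path Output file.
#' @param dialect One of `"afa"`, `"stockholm"`, `"clustal"`.
#' @export
write_alignment <- function(msa, path, dialect = c("afa", "stockholm", "clustal")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(msa, "aa_msa"))
  con <- file(path, "w")
  on.exit(close(con))
  switch(dialect,
    afa = {
      for (id in msa$ids) {
        writeLines(paste0(">", id), con)
        s <- msa$rows[[id]]
        starts <- seq(1L, nchar(s), by = 60L)
        writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con)
      }
    },
    stockholm = {
      writeLines("# STOCKHOLM 1.0", con)
      w <- max(nchar(msa$ids))
      for (id in msa$ids)
        writeLines(sprintf("%-*s %s", w, id, msa$rows[[id]]), con)
      writeLines("//", con)
    },
    clustal = {
      writeLines(c("CLUSTAL W multiple sequence alignment (impscan)", ""), con)
      w <- max(nchar(msa$ids))
      starts <- seq(1L, msa$n_columns, by = 60L)
      for (st in starts) {
        for (id in msa$ids) {
          chunk <- substring(msa$rows[[id]], st, min(st + 59L, msa$n_columns))
          writeLines(sprintf("%-*s %s", w, id, chunk), con)
        }
        writeLines("", con)
      }
    }
  )
  invisible(path)
}

#' Remove gaps from one alignment row
#'
#' @param msa An [aa_msa].
#' @param id Row identifier.
#' @return An [aa_seq] with the gaps stripped.
#' @export
msa_degap <- function(msa, id) {
  stopifnot(inherits(msa, "aa_msa"))
  if (!id %in% msa$ids) stop("no row '", id, "' in alignment")
  aa_seq(id, gsub("-", "", msa$rows[[id]], fixed = TRUE))
}

#' Average molecular mass of a protein monomer
#'
#' Sum of average residue masses plus one water (equivalently, free
#' amino-acid masses minus one water per peptide bond), for the unmodified
#' monomer including the initiator methionine if present in the sequence.
#'
#' @param record An [aa_seq] (or residue string).
#' @return Mass in g/mol.
#' @examples
#' average_mass(aa_seq("g", "G"))   # 75.07
#' @export
average_mass <- function(record) {
  residues <- if (inherits(record, "aa_seq")) record$residues
              else toupper(as.character(record))
  chars <- strsplit(residues, "", fixed = TRUE)[[1L]]
  if (any(chars == "X"))
    stop("ambiguous residue: cannot compute mass of a sequence containing X")
  check_residues(residues)
  sum(AA_RESIDUE_MASS[chars]) + WATER_MASS
}
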