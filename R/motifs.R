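# Position-anchored residue motifs for the five IMPase-like paralog groups
# (HisN, Cg0911, SuhB, ImpA, CysQ). Positions are 1-based coordinates in
# each family's reference protein. Six motifs discriminate the HolPase
# family (HisN) from the four paralog groups; motif 5 (conserved Asp at
# reference position 191 flanked by aromatics) is the most diagnostic.

#' Residue class membership
#'
#' @param name One of `"aromatic"` (F, Y, W), `"aromatic_or_his"`
#'   (F, Y, W, H), `"small"` (G, A), `"polar_ST"` (S, T), `"acidic"` (D, E),
#'   `"any"` (the 20 standard residues), or a string of explicit residues
#'   (e.g. `"K"`, `"DE"`).
#' @return Character vector of member residues.
#' @export
residue_class <- function(name) {
  switch(name,
    aromatic = c("F", "Y", "W"),
    aromatic_or_his = c("F", "Y", "W", "H"),
    small = c("G", "A"),
    polar_ST = c("S", "T"),
    acidic = c("D", "E"),
    any = AA_STANDARD,
    {
      members <- strsplit(name, "", fixed = TRUE)[[1L]]
      if (!all(members %in% AA_STANDARD))
        stop("unknown residue class: '", name, "'")
      members
    })
}

#' Define one motif position
#'
#' @param ref_pos 1-based position in the family reference protein.
#' @param allowed Residue class name or explicit residue string (see
#'   [residue_class]).
#' @param level `"required"` (drives presence) or `"preferred"` (counts
#'   toward the preferred-fraction threshold).
#' @param forbidden Optional string of residues that must not occur at the
#'   position (disjoint from `allowed` members after exclusion).
#' @return A `motif_position` list.
#' @export
motif_position <- function(ref_pos, allowed = "any",
                           level = c("required", "preferred"),
                           forbidden = NULL) {
  level <- match.arg(level)
  stopifnot(is.numeric(ref_pos), ref_pos >= 1)
  members <- residue_class(allowed)
  forb <- if (is.null(forbidden)) character(0)
          else strsplit(forbidden, "", fixed = TRUE)[[1L]]
  members <- setdiff(members, forb)
  if (!length(members)) stop("allowed and forbidden sets leave no residue")
  structure(list(ref_pos = as.integer(ref_pos), allowed = members,
                 class_name = allowed, level = level, forbidden = forb),
            class = "motif_position")
}

#' Define a position-anchored motif
#'
#' A motif is present when all required positions (and pair rules) of its
#' main position list, or of any alternative list, are satisfied and the
#' satisfied fraction of preferred outcomes reaches the threshold.
#'
#' @param family Family name (HisN, Cg0911, SuhB, ImpA, CysQ).
#' @param index Motif index 1-6.
#' @param positions List of [motif_position]s (the main variant).
#' @param alternatives List of alternative variants, each a list with
#'   elements `positions` and optional `pair_rules` (OR semantics).
#' @param pair_rules List of two-position rules for the main variant; each
#'   is a list with `type` (`"xor_aromatic_small"`: exactly one of the two
#'   positions aromatic is required, the counterpart being G/A is preferred;
#'   or `"forbidden_pair"`: the given residues at the two consecutive
#'   positions veto the motif) and `positions` (length-2 integer).
#' @param preferred_fraction_threshold Fraction of preferred outcomes that
#'   must be satisfied, default 0.7.
#' @return A `motif_def`.
#' @export
motif_def <- function(family, index, positions, alternatives = list(),
                      pair_rules = list(),
                      preferred_fraction_threshold = 0.7) {
  n_req <- sum(vapply(positions, function(p) p$level == "required", logical(1)))
  n_req <- n_req + sum(vapply(pair_rules, function(r)
    identical(r$type, "xor_aromatic_small"), logical(1)))
  if (n_req < 1L) stop("a motif needs at least one required position")
  structure(list(family = family, index = as.integer(index),
                 positions = positions, alternatives = alternatives,
                 pair_rules = pair_rules,
                 preferred_fraction_threshold = preferred_fraction_threshold),
            class = "motif_def")
}

pair_rule <- function(type, positions, residues = NULL) {
  list(type = type, positions = as.integer(positions), residues = residues)
}

#' Shipped motif rule set
#'
#' Returns the built-in position-anchored motif definitions for the five
#' IMPase-like families, in each family's reference coordinates. HisN rules
#' encode all six HolPase motifs, including the alternative motif 1 found
#' in some proteobacterial orthologs; the paralog families carry their
#' discriminating positions (e.g. the SuhB RR + GSAAL motif 5, the ImpA
#' Arg pair interspaced by one residue, the CysQ Ser64 motif-2 variant and
#' Pro219) plus the residues shared by all IMPase-like proteins. CysQ ships
#' five motifs (its motif 4 has no positional definition here).
#'
#' @return Named list: family -> list of [motif_def].
#' @export
builtin_rules <- function() {
  p <- motif_position
  hisn <- list(
    motif_def("HisN", 1L,
      positions = list(
        p(36, "K"), p(38, "D", "preferred"), p(40, "polar_ST"),
        p(41, "P", "preferred"), p(42, "V"), p(43, "polar_ST"),
        p(46, "D")),
      alternatives = list(
        list(positions = list(p(34, "K"), p(40, "aromatic"), p(41, "D"),
                              p(42, "V"), p(43, "T"), p(46, "D"))),
        list(positions = list(p(35, "K"), p(40, "aromatic"), p(41, "D"),
                              p(42, "V"), p(43, "T"), p(46, "D"))))),
    motif_def("HisN", 2L,
      positions = list(p(68, "G", "preferred"), p(69, "E"), p(70, "E"))),
    motif_def("HisN", 3L,
      positions = list(p(85, "D"), p(87, "I"), p(88, "D"), p(90, "T"),
                       p(91, "K", "preferred"),
                       p(93, "aromatic", "preferred"))),
    motif_def("HisN", 4L,
      positions = list(p(95, "R", "preferred"), p(96, "G"), p(98, "P"),
                       p(100, "aromatic"), p(102, "T"), p(103, "L"))),
    motif_def("HisN", 5L,
      positions = list(p(187, "RVL", "preferred"),
                       p(190, "G", "preferred"), p(191, "DE"),
                       p(192, "aromatic", "preferred"), p(193, "aromatic"),
                       p(195, "aromatic_or_his")),
      pair_rules = list(
        pair_rule("xor_aromatic_small", c(188L, 189L)),
        pair_rule("forbidden_pair", c(195L, 196L), c("D", "L")))),
    motif_def("HisN", 6L,
      positions = list(p(215, "D"), p(219, "any", forbidden = "G")))
  )
  shared <- function(fam) list(
    motif_def(fam, 1L, positions = list(p(46, "D"))),
    motif_def(fam, 2L,
      positions = list(p(68, "G", "preferred"), p(69, "E"), p(70, "E"))),
    motif_def(fam, 3L,
      positions = list(p(85, "D"), p(87, "I"), p(88, "D"), p(90, "T")))
  )
  # Positions 191-196 below are in the shared (HisN-frame) coordinates of
  # the schematic references: no Asp/Glu at 191, and the Asp+Leu pair at
  # the positions homologous to SuhB 203/204.
  cg0911 <- c(shared("Cg0911"), list(
    motif_def("Cg0911", 4L, positions = list(p(96, "G"))),
    motif_def("Cg0911", 5L,
      positions = list(p(191, "any", forbidden = "DE"),
                       p(195, "D"), p(196, "L"))),
    motif_def("Cg0911", 6L,
      positions = list(p(215, "D"), p(219, "G")))))
  impa <- c(shared("ImpA"), list(
    motif_def("ImpA", 4L, positions = list(p(96, "G"))),
    motif_def("ImpA", 5L,
      positions = list(p(179, "R"), p(181, "R"),
                       p(191, "any", forbidden = "DE"),
                       p(195, "D", "preferred"), p(196, "L", "preferred"))),
    motif_def("ImpA", 6L,
      positions = list(p(215, "D"), p(219, "G")))))
  suhb <- c(shared("SuhB"), list(
    motif_def("SuhB", 4L, positions = list(p(96, "G"))),
    motif_def("SuhB", 5L,
      positions = list(p(195, "R"), p(196, "R"),
                       p(197, "G", "preferred"), p(198, "S", "preferred"),
                       p(199, "A", "preferred"), p(200, "A", "preferred"),
                       p(201, "L", "preferred"),
                       p(203, "D", "preferred"), p(204, "L", "preferred"))),
    motif_def("SuhB", 6L,
      positions = list(p(215, "D"), p(219, "G")))))
  cysq <- list(
    motif_def("CysQ", 1L, positions = list(p(46, "D"))),
    motif_def("CysQ", 2L,
      positions = list(p(63, "L", "preferred"), p(64, "S"),
                       p(65, "E"), p(66, "E"))),
    motif_def("CysQ", 3L,
      positions = list(p(85, "D"), p(87, "I"), p(88, "D"), p(90, "T"))),
    motif_def("CysQ", 5L,
      positions = list(p(191, "any", forbidden = "DE"),
                       p(192, "any", forbidden = "FYW"),
                       p(193, "any", forbidden = "FYW"),
                       p(194, "any", forbidden = "FYW"),
                       p(195, "any", forbidden = "FYW"))),
    motif_def("CysQ", 6L,
      positions = list(p(215, "D"), p(219, "P")))
  )
  list(HisN = hisn, Cg0911 = cg0911, ImpA = impa, SuhB = suhb, CysQ = cysq)
}

# --- YAML serialization ----------------------------------------------------

pos_to_list <- function(p) {
  out <- list(ref_pos = p$ref_pos, allowed = p$class_name, level = p$level)
  if (length(p$forbidden)) out$forbidden <- paste(p$forbidden, collapse = "")
  out
}
pos_from_list <- function(x) {
  motif_position(x$ref_pos, x$allowed, x$level,
                 forbidden = x$forbidden)
}
def_to_list <- function(d) {
  list(family = d$family, index = d$index,
       positions = lapply(d$positions, pos_to_list),
       alternatives = lapply(d$alternatives, function(a)
         list(positions = lapply(a$positions, pos_to_list))),
       pair_rules = lapply(d$pair_rules, function(r)
         list(type = r$type, positions = r$positions,
              residues = r$residues)),
       preferred_fraction_threshold = d$preferred_fraction_threshold)
}
def_from_list <- function(x) {
  motif_def(x$family, x$index,
            positions = lapply(x$positions, pos_from_list),
            alternatives = lapply(x$alternatives, function(a)
              list(positions = lapply(a$positions, pos_from_list))),
            pair_rules = lapply(x$pair_rules, function(r)
              pair_rule(r$type, unlist(r$positions), unlist(r$residues))),
            preferred_fraction_threshold =
              x$preferred_fraction_threshold %||% 0.7)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write motif rules to a YAML file
#' @param rules Named list family -> list of [motif_def] (as from
#'   [builtin_rules]).
#' @param path Output path.
#' @export
write_motif_rules <- function(rules, path) {
  yaml::write_yaml(lapply(rules, function(defs) lapply(defs, def_to_list)),
                   path)
  invisible(path)
}

#' Read motif rules from a YAML file
#' @param path YAML file written by [write_motif_rules] (or hand-edited in
#'   the same schema).
#' @return Named list family -> list of [motif_def].
#' @export
read_motif_rules <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(defs) lapply(defs, def_from_list))
}
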