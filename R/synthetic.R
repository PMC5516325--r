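# Seeded generators: ortholog families with controllable conservation and
# motif implant/ablation, kinetic assay data, and toy taxonomies.

# Background amino-acid frequencies (BLOSUM62 marginals), used for random
# residues, HMM null models and pseudocounts.
BG_FREQS <- local({
  f <- c(A = 0.0787, R = 0.0512, N = 0.0448, D = 0.0536, C = 0.0125,
         Q = 0.0395, E = 0.0668, G = 0.0708, H = 0.0224, I = 0.0589,
         L = 0.0964, K = 0.0593, M = 0.0237, F = 0.0397, P = 0.0492,
         S = 0.0687, T = 0.0541, W = 0.0110, Y = 0.0292, V = 0.0686)
  f / sum(f)
})

# Default random seed for examples and simulations.
DEFAULT_SEED <- 1069L

canonical_residue <- function(p) {
  # Deterministic representative residue for a motif position.
  if (length(p$allowed) == 1L) return(p$allowed)
  pick <- switch(p$class_name,
    polar_ST = "T", aromatic = "Y", aromatic_or_his = "Y",
    small = "A", acidic = "D", NULL)
  if (!is.null(pick) && pick %in% p$allowed) return(pick)
  p$allowed[1L]
}

#' Synthetic family reference scaffold
#'
#' Builds a deterministic reference sequence for one family that satisfies
#' every shipped motif rule of that family: all motif positions carry a
#' canonical residue of their allowed class, the 188/189 aromatic/small pair
#' is set to A/Y, and remaining positions are drawn from the background
#' distribution. These scaffolds stand in for the real *C. glutamicum*
#' reference proteins in simulations and tests; they are synthetic and share
#' nothing with the database sequences beyond the rule positions.
#'
#' @param family Family name.
#' @param length Scaffold length (default 260 residues).
#' @param rules Rule set, default [builtin_rules].
#' @param seed Integer seed (per-family offset applied internally).
#' @return An [aa_seq] with attributes `categories` (per-position
#'   conservation category) and `protected` (motif-constrained positions).
#' @export
make_family_reference <- function(family, length = 260L,
                                  rules = builtin_rules(),
                                  seed = DEFAULT_SEED) {
  defs <- rules[[family]]
  if (is.null(defs)) stop("no rules for family '", family, "'")
  fam_offset <- match(family, names(rules))
  withr_seed(seed + 7919L * fam_offset, {
    chars <- sample(names(BG_FREQS), length, replace = TRUE, prob = BG_FREQS)
    categories <- rep("variable", length)
    other <- sample(c("moderate", "variable"), length, replace = TRUE)
    categories[] <- other
    protected <- integer(0)
    preferred <- integer(0)
    for (d in defs) {
      for (p in d$positions) {
        if (p$ref_pos > length) stop("rule position beyond scaffold length")
        chars[p$ref_pos] <- canonical_residue(p)
        categories[p$ref_pos] <- if (p$level == "required") "strict" else "high"
        if (p$level == "required") protected <- c(protected, p$ref_pos)
        else preferred <- c(preferred, p$ref_pos)
      }
      for (r in d$pair_rules) {
        if (identical(r$type, "xor_aromatic_small")) {
          chars[r$positions[1L]] <- "A"
          chars[r$positions[2L]] <- "Y"
          categories[r$positions] <- "strict"
          protected <- c(protected, r$positions)
        } else if (identical(r$type, "forbidden_pair")) {
          if (identical(chars[r$positions[1L]], r$residues[1L]) &&
              identical(chars[r$positions[2L]], r$residues[2L]))
            chars[r$positions[2L]] <- "A"
        }
      }
    }
    ref <- aa_seq(paste0(family, "_ref"), paste(chars, collapse = ""),
                  "synthetic family reference scaffold")
    attr(ref, "categories") <- categories
    attr(ref, "protected") <- sort(unique(protected))
    attr(ref, "preferred") <- sort(unique(setdiff(preferred, protected)))
    ref
  })
}

# Run code under a local RNG seed without disturbing the caller's RNG.
withr_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Specify a synthetic ortholog family
#'
#' @param family Family name.
#' @param reference Reference [aa_seq] carrying `categories`/`protected`
#'   attributes (default the synthetic scaffold for `family`).
#' @param rates Named per-category substitution rates; defaults
#'   strict 0, high 0.05, moderate 0.3, variable 0.7.
#' @param indel_rate Per-column indel probability (variable columns only).
#' @param n Number of sequences.
#' @param ablations List of `list(motif = index, position = ref_pos,
#'   replacement = residue)` applied to every simulated sequence even at
#'   protected positions.
#' @param protect_preferred Hold preferred motif positions fixed as well as
#'   required ones (default TRUE): real ortholog families keep all six
#'   motifs detectable in essentially every member, and sensitivity to
#'   preferred-position variation is probed by explicit ablations instead.
#' @param seed Mandatory integer seed.
#' @return A `family_sim_spec`.
#' @export
family_sim_spec <- function(family, reference = NULL,
                            rates = c(strict = 0, high = 0.05,
                                      moderate = 0.3, variable = 0.7),
                            indel_rate = 0.01, n = 20L,
                            ablations = list(), protect_preferred = TRUE,
                            seed = DEFAULT_SEED) {
  if (is.null(reference)) reference <- make_family_reference(family)
  stopifnot(all(rates >= 0 & rates <= 1), n >= 1, !is.null(seed))
  for (ab in ablations)
    if (ab$position < 1 || ab$position > nchar(reference$residues))
      stop("ablation position ", ab$position, " outside the reference")
  structure(list(family = family, reference = reference, rates = rates,
                 indel_rate = indel_rate, n = as.integer(n),
                 ablations = ablations,
                 protect_preferred = isTRUE(protect_preferred),
                 seed = as.integer(seed)),
            class = "family_sim_spec")
}

# BLOSUM62-conditional substitution distribution: likelier exchanges are
# more probable. P(b | a) proportional to bg_b * 2^(s(a,b)/2), b != a.
subst_distributions <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    m <- get_submat("BLOSUM62")[AA_STANDARD, AA_STANDARD]
    out <- lapply(AA_STANDARD, function(a) {
      w <- BG_FREQS * 2^(m[a, names(BG_FREQS)] / 2)
      w[a] <- 0
      w / sum(w)
    })
    names(out) <- AA_STANDARD
    cache <<- out
    cache
  }
})

#' Simulate an ortholog family from a reference
#'
#' Each sequence is mutated from the reference with per-column substitution
#' rates set by the column's conservation category; substitutions are drawn
#' from BLOSUM62-conditional exchange distributions. Positions required by
#' the family's motifs are held fixed unless explicitly ablated. Indels
#' occur only in variable columns (geometric length, p = 0.5, capped at 5).
#'
#' @param spec A [family_sim_spec].
#' @return List with `records` (list of [aa_seq]) and `labels`
#'   (data.frame `id`, `family`), deterministic given the spec's seed.
#' @export
simulate_family <- function(spec) {
  stopifnot(inherits(spec, "family_sim_spec"))
  ref <- spec$reference
  chars0 <- strsplit(ref$residues, "", fixed = TRUE)[[1L]]
  categories <- attr(ref, "categories") %||% rep("variable", length(chars0))
  protected <- attr(ref, "protected") %||% integer(0)
  if (spec$protect_preferred)
    protected <- sort(union(protected, attr(ref, "preferred") %||% integer(0)))
  sub_dist <- subst_distributions()
  ablate_pos <- vapply(spec$ablations, function(a) as.integer(a$position),
                       integer(1))
  withr_seed(spec$seed, {
    records <- vector("list", spec$n)
    for (s in seq_len(spec$n)) {
      chars <- chars0
      for (ab in spec$ablations)
        chars[ab$position] <- toupper(ab$replacement)
      pieces <- as.list(chars)
      for (j in seq_along(chars)) {
        if (j %in% ablate_pos) next
        rate <- spec$rates[[categories[j]]]
        if (!(j %in% protected) && rate > 0 && stats::runif(1) < rate) {
          a <- chars[j]
          if (a %in% names(sub_dist))
            pieces[[j]] <- sample(names(sub_dist[[a]]), 1L,
                                  prob = sub_dist[[a]])
        }
        if (categories[j] == "variable" && spec$indel_rate > 0 &&
            stats::runif(1) < spec$indel_rate) {
          len <- min(stats::rgeom(1, 0.5) + 1L, 5L)
          if (stats::runif(1) < 0.5) {
            ins <- paste(sample(names(BG_FREQS), len, replace = TRUE,
                                prob = BG_FREQS), collapse = "")
            pieces[[j]] <- paste0(pieces[[j]], ins)
          } else {
            pieces[[j]] <- ""
          }
        }
      }
      id <- sprintf("%s_sim%03d", spec$family, s)
      records[[s]] <- aa_seq(id, paste(unlist(pieces), collapse = ""))
    }
    list(records = as_aa_seq_list(records),
         labels = data.frame(
           id = vapply(records, `[[`, character(1), "id"),
           family = spec$family, stringsAsFactors = FALSE))
  })
}

#' Specify a synthetic kinetic assay
#'
#' @param type `"hill"` (substrate saturation) or `"activation"` (effector
#'   stimulation).
#' @param params For `"hill"`: `vmax` (uM/s), `s50` (uM), `h`; for
#'   `"activation"`: `v0`, `fold`, `k_act` (mM).
#' @param concentrations Concentration series (uM for hill, mM for
#'   activation); at least 5 values.
#' @param replicates Replicates per concentration.
#' @param cv Multiplicative noise coefficient of variation (default 0.05).
#' @param seed Mandatory integer seed.
#' @return A `kinetics_sim_spec`.
#' @export
kinetics_sim_spec <- function(type = c("hill", "activation"), params,
                              concentrations, replicates = 3L, cv = 0.05,
                              seed = DEFAULT_SEED) {
  type <- match.arg(type)
  stopifnot(length(concentrations) >= 5L, all(unlist(params) > 0),
            all(concentrations >= 0), !is.null(seed))
  structure(list(type = type, params = params,
                 concentrations = sort(concentrations),
                 replicates = as.integer(replicates), cv = cv,
                 seed = as.integer(seed)),
            class = "kinetics_sim_spec")
}

hill_model <- function(S, vmax, s50, h) vmax * S^h / (s50^h + S^h)
activation_model <- function(x, v0, fold, k_act)
  v0 * (1 + (fold - 1) * x / (k_act + x))

#' Simulate kinetic assay rates
#'
#' Rates are the model value times multiplicative Gaussian noise
#' `(1 + cv * z)`, seeded and reproducible.
#'
#' @param spec A [kinetics_sim_spec].
#' @param timepoints Optional vector of sampling times (minutes); when
#'   given, the rate table is expanded into noiseless phosphate-release
#'   time courses (`pi = rate * t`) for [rate_from_timecourse].
#' @return A data.frame with columns `conc`, `replicate`, `rate` (and
#'   `timepoint_min`, `pi` when expanded).
#' @export
simulate_kinetics <- function(spec, timepoints = NULL) {
  stopifnot(inherits(spec, "kinetics_sim_spec"))
  model <- switch(spec$type,
    hill = function(S) hill_model(S, spec$params$vmax, spec$params$s50,
                                  spec$params$h),
    activation = function(x) activation_model(x, spec$params$v0,
                                              spec$params$fold,
                                              spec$params$k_act))
  withr_seed(spec$seed, {
    grid <- expand.grid(replicate = seq_len(spec$replicates),
                        conc = spec$concentrations)
    mu <- model(grid$conc)
    z <- stats::rnorm(nrow(grid))
    rates <- pmax(mu * (1 + spec$cv * z), 0)
    out <- data.frame(conc = grid$conc, replicate = grid$replicate,
                      rate = rates)
    if (!is.null(timepoints)) {
      out <- do.call(rbind, lapply(seq_len(nrow(out)), function(i) {
        data.frame(conc = out$conc[i], replicate = out$replicate[i],
                   rate = out$rate[i], timepoint_min = timepoints,
                   pi = out$rate[i] * timepoints)
      }))
    }
    out
  })
}

#' Build a deterministic toy taxonomy
#'
#' @param n_phyla,n_families,n_genera,n_species Shape of the tree: families
#'   per phylum, genera per family, species per genus.
#' @param presence Optional character vector of species-level presence
#'   values (`positive`/`negative`/`unknown`), recycled across species in
#'   depth-first order; default all `"unknown"`.
#' @return A `taxon_node` tree rooted at a phylum (or a `"domain"` root
#'   when `n_phyla > 1`) with species presence assigned.
#' @export
make_toy_taxonomy <- function(n_phyla = 1L, n_families = 2L, n_genera = 10L,
                              n_species = 3L, presence = "unknown") {
  counter <- 0L
  next_presence <- function() {
    counter <<- counter + 1L
    presence[((counter - 1L) %% length(presence)) + 1L]
  }
  phyla <- lapply(seq_len(n_phyla), function(p) {
    fams <- lapply(seq_len(n_families), function(f) {
      genera <- lapply(seq_len(n_genera), function(g) {
        species <- lapply(seq_len(n_species), function(s)
          taxon_node(sprintf("sp_p%d_f%d_g%d_s%d", p, f, g, s), "species",
                     presence = next_presence()))
        taxon_node(sprintf("genus_p%d_f%d_g%d", p, f, g), "genus", species)
      })
      taxon_node(sprintf("family_p%d_f%d", p, f), "family", genera)
    })
    taxon_node(sprintf("phylum_p%d", p), "phylum", fams)
  })
  if (n_phyla == 1L) phyla[[1L]]
  else taxon_node("bacteria", "domain", phyla)
}
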