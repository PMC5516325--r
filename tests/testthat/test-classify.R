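test_that("reference sequences classify to their own family", {
  for (fam in names(REFS)) {
    cl <- classify_sequence(REFS[[fam]], REFS, RULES)
    expect_equal(cl$best_family, fam)
    expect_equal(cl$assignment, fam)
    expect_equal(cl$triage_class, "consistent")
    expect_equal(cl$holpase_call, if (fam == "HisN") "yes" else "no")
  }
})

test_that("HisN-like sequences lacking motif 5 are class 2 and not HolPases", {
  sim <- simulate_family(family_sim_spec(
    "HisN", n = 3, seed = 1069,
    ablations = list(list(motif = 5L, position = 191L, replacement = "A"))))
  for (s in sim$records) {
    cl <- classify_sequence(s, REFS, RULES)
    expect_equal(cl$best_family, "HisN")
    expect_false(cl$motif5_present)
    expect_equal(cl$triage_class, "class2")
    expect_equal(cl$holpase_call, "no")
    expect_equal(cl$assignment, "unassigned-IMPase-like")
  }
})

test_that("SuhB orthologs misannotated as HolPases are class 3 and reassigned", {
  sim <- simulate_family(family_sim_spec("SuhB", n = 3, seed = 1069))
  for (s in sim$records) {
    cl <- classify_sequence(s, REFS, RULES, claimed_annotation = "HolPase")
    expect_equal(cl$best_family, "SuhB")
    expect_equal(cl$triage_class, "class3")
    expect_equal(cl$assignment, "SuhB")
    expect_equal(cl$holpase_call, "no")
  }
})

test_that("distant orthologs with intact motifs are class 1 but still HolPases", {
  # heavy substitution outside the motif positions drives the overall
  # alignment score below the ortholog-identification threshold while the
  # motifs stay intact ("moderate overall similarity")
  sim <- simulate_family(family_sim_spec(
    "HisN", n = 4,
    rates = c(strict = 0, high = 0, moderate = 0.85, variable = 0.95),
    indel_rate = 0.03, seed = 1069))
  cl <- classify_sequence(sim$records[[1L]], REFS, RULES)
  expect_equal(cl$best_family, "HisN")
  expect_lt(cl$score, DEFAULT_SCORE_THRESHOLD)
  expect_false(cl$score_above_threshold)
  expect_equal(cl$triage_class, "class1")
  expect_equal(cl$holpase_call, "yes")
})

test_that("classification is deterministic and ties break canonically", {
  s <- simulate_family(family_sim_spec("ImpA", n = 1, seed = 7))$records[[1L]]
  a <- classify_sequence(s, REFS, RULES)
  b <- classify_sequence(s, REFS, RULES)
  expect_identical(a[c("best_family", "assignment", "triage_class", "score")],
                   b[c("best_family", "assignment", "triage_class", "score")])

  twin_refs <- REFS
  twin_refs$Cg0911$residues <- twin_refs$HisN$residues
  expect_warning(cl <- classify_sequence(REFS$HisN, twin_refs, RULES),
                 "tie")
  expect_equal(cl$best_family, "HisN") # canonical order HisN first
})

test_that("missing references are reported", {
  expect_error(classify_sequence(REFS$HisN, REFS[c("HisN", "SuhB")], RULES),
               "missing reference")
})

test_that("taxonomy roll-up implements the genus / >=3 / half rules", {
  genus <- function(pres)
    taxon_node("g", "genus", lapply(seq_along(pres), function(i)
      taxon_node(paste0("s", i), "species", presence = pres[i])))
  g <- rollup_taxonomy(genus(c("positive", "negative", "negative")))
  expect_equal(g$presence, "positive")
  expect_equal(rollup_taxonomy(genus(c("negative", "negative")))$presence,
               "negative")
  expect_equal(rollup_taxonomy(genus(rep("unknown", 3)))$presence, "unknown")

  fam_of <- function(n_pos, n_neg, n_unk = 0L) {
    genera <- c(
      lapply(seq_len(n_pos), function(i) genus("positive")),
      lapply(seq_len(n_neg), function(i) genus("negative")),
      lapply(seq_len(n_unk), function(i) genus("unknown")))
    genera <- lapply(seq_along(genera), function(i) {
      g <- genera[[i]]; g$name <- paste0("g", i); g
    })
    rollup_taxonomy(taxon_node("f", "family", genera))$presence
  }
  expect_equal(fam_of(3L, 7L), "positive")  # >= 3 rule
  expect_equal(fam_of(2L, 8L), "negative")
  expect_equal(fam_of(2L, 2L), "positive")  # half rule
  expect_equal(fam_of(1L, 2L), "negative")
  # unknown genera leave the half-rule denominator
  expect_equal(fam_of(2L, 2L, n_unk = 6L), "positive")
})

test_that("roll-up is monotone in added positive species", {
  impscan:::withr_seed(1069, {
    for (rep in 1:5) {
      pres <- sample(c("positive", "negative", "unknown"), 60,
                     replace = TRUE, prob = c(0.3, 0.5, 0.2))
      tree <- make_toy_taxonomy(n_families = 2, n_genera = 5, n_species = 6,
                                presence = pres)
      before <- taxonomy_to_table(rollup_taxonomy(tree))
      # flip one negative species to positive
      flip_one <- function(node) {
        if (node$rank == "species" && node$presence == "negative") {
          node$presence <- "positive"
          attr(node, "flipped") <- TRUE
          return(node)
        }
        for (i in seq_along(node$children)) {
          ch <- flip_one(node$children[[i]])
          node$children[[i]] <- ch
          if (isTRUE(attr(ch, "flipped"))) {
            attr(node, "flipped") <- TRUE
            break
          }
        }
        node
      }
      after <- taxonomy_to_table(rollup_taxonomy(flip_one(tree)))
      was_pos <- before$lineage[before$presence == "positive"]
      still_pos <- after$lineage[after$presence == "positive"]
      expect_true(all(was_pos %in% still_pos))
    }
  })
})

test_that("presence tables round trip through TSV", {
  tree <- make_toy_taxonomy(n_families = 2, n_genera = 3, n_species = 2,
                            presence = c("positive", "negative", "unknown"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_presence_tsv(tree, f)
  back <- read_presence_tsv(f, ranks = c("phylum", "family", "genus",
                                         "species"))
  orig <- taxonomy_to_table(tree)
  rebuilt <- taxonomy_to_table(back)
  orig_sp <- orig[orig$rank == "species", ]
  rebuilt_sp <- rebuilt[rebuilt$rank == "species", ]
  expect_equal(rebuilt_sp$presence[order(rebuilt_sp$lineage)],
               orig_sp$presence[order(orig_sp$lineage)])
})
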