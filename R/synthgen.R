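# Synthetic chemogenomic worlds -----------------------------------------------
#
# A "world" is the bundle of tables the modeling pipeline consumes: a
# long-format perturbation Z-score table, drug SMILES, gene->GO annotations,
# a cell-line mutation matrix, methylated/unmethylated probe intensities,
# histology labels, and a pro-/anti-longevity gene label table. Worlds are
# fully seeded and carry planted drug-gene regulation signal so classifier
# recovery can be tested end to end without any external download.

#' Configuration for a synthetic chemogenomic world
#'
#' Defines the size and signal structure of a generated world. The defaults
#' describe the study conditions used throughout the package: a 40-drug x
#' 50-gene x 5-cell-line screen in which 220 drug-gene pairs (110 per
#' direction, i.e. 5.5% of all pairs per direction) carry a planted Z-score
#' shift of +/- `effect_size`. Planted pairs form a product structure per
#' direction -- a small set of active drugs crossed with a module of
#' responsive genes, as when a compound class hits a co-regulated pathway --
#' so the signal is recoverable from drug and gene descriptors by a shallow
#' conjunctive rule. The planted prevalence sits slightly above the
#' 5% labeling fraction so that the labeled tail of each cell line is
#' saturated by true signal, and `effect_size = 5` corresponds to a strong,
#' unambiguous perturbagen response. The longevity label fractions default to
#' 397/889 pro and 492/889 anti, the proportions of the human-mapped GenAge
#' aging-gene set, so that an 889-gene world reproduces the canonical
#' 397 pro / 492 anti split.
#'
#' @param n_drugs,n_genes,n_cells Number of drugs, genes and (cancer) cell
#'   lines in the world.
#' @param n_go_terms Number of GO terms available for gene annotation.
#' @param n_mutation_markers Number of binary mutation markers per cell line.
#' @param n_cpg_sites Number of CpG sites with intensity measurements.
#' @param n_histology_classes Number of histology classes the cancer cell
#'   lines are assigned to (round-robin).
#' @param n_normal_cells Number of additional normal (non-cancer) cell lines;
#'   these appear in the intensity tables only, never in perturbations,
#'   mutations, or histology.
#' @param frac_pro,frac_anti Fractions of genes labeled pro- and
#'   anti-longevity; `floor(frac * n_genes)` genes receive each label and
#'   `frac_pro + frac_anti` must not exceed 1.
#' @param planted_pairs Number of drug-gene pairs with a forced regulation
#'   direction (alternating up/down); must not exceed `n_drugs * n_genes`.
#' @param effect_size Z-score shift applied to planted pairs (+ for up,
#'   - for down), consistently across all cell lines.
#' @param frac_alt_unit Fraction of perturbation records carrying a non-µM
#'   dose unit ("nM"), exercising the dose-unit filter.
#' @param frac_alt_time Fraction of records carrying a 6-h treatment time
#'   instead of 24 h, exercising the treatment-time filter.
#' @param frac_informative_cpg Fraction of CpG sites whose beta distribution
#'   differs systematically by histology class (so methylation feature
#'   selection has signal to find).
#' @param seed Integer seed; identical configurations generate byte-identical
#'   worlds.
#'
#' @return A `synth_config` list, validated.
#' @export
#' @examples
#' cfg <- synth_config(n_drugs = 4, n_genes = 10, n_cells = 2,
#'                     planted_pairs = 4, seed = 1)
#' world <- gen_world(cfg)
#' nrow(world$perturbations)
synth_config <- function(n_drugs = 40, n_genes = 50, n_cells = 5,
                         n_go_terms = 60, n_mutation_markers = 12,
                         n_cpg_sites = 60, n_histology_classes = 3,
                         n_normal_cells = 2,
                         frac_pro = 397 / 889, frac_anti = 492 / 889,
                         planted_pairs = 220, effect_size = 5,
                         frac_alt_unit = 0.1, frac_alt_time = 0.1,
                         frac_informative_cpg = 0.3,
                         seed = 1L) {
  cfg <- list(
    n_drugs = as.integer(n_drugs), n_genes = as.integer(n_genes),
    n_cells = as.integer(n_cells), n_go_terms = as.integer(n_go_terms),
    n_mutation_markers = as.integer(n_mutation_markers),
    n_cpg_sites = as.integer(n_cpg_sites),
    n_histology_classes = as.integer(n_histology_classes),
    n_normal_cells = as.integer(n_normal_cells),
    frac_pro = frac_pro, frac_anti = frac_anti,
    planted_pairs = as.integer(planted_pairs), effect_size = effect_size,
    frac_alt_unit = frac_alt_unit, frac_alt_time = frac_alt_time,
    frac_informative_cpg = frac_informative_cpg,
    seed = as.integer(seed)
  )
  counts <- c("n_drugs", "n_genes", "n_cells", "n_go_terms",
              "n_mutation_markers", "n_cpg_sites", "n_histology_classes",
              "n_normal_cells", "planted_pairs")
  for (nm in counts) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 0) {
      abort(sprintf("`%s` must be a nonnegative count", nm))
    }
  }
  if (cfg$frac_pro < 0 || cfg$frac_anti < 0 || cfg$frac_pro + cfg$frac_anti > 1 + 1e-12) {
    abort("`frac_pro` and `frac_anti` must be nonnegative with sum <= 1")
  }
  if (cfg$effect_size < 0) abort("`effect_size` must be >= 0")
  if (cfg$planted_pairs > cfg$n_drugs * cfg$n_genes) {
    abort("`planted_pairs` cannot exceed n_drugs * n_genes")
  }
  structure(cfg, class = "synth_config")
}

# Planted pair sampling must be the first RNG use under the config seed so
# that planted_truth() can reproduce it independently of gen_world().
#
# Planted pairs form a product structure per direction: a small set of
# active drugs crossed with a module of responsive genes (truncated to the
# requested count). This emulates a compound class hitting a co-regulated
# gene module and makes the planted signal recoverable by a shallow
# drug-AND-gene rule rather than by memorizing arbitrary pair identities.
plant_pairs <- function(config) {
  drugs <- id_series("DRUG", config$n_drugs)
  genes <- id_series("GENE", config$n_genes)
  if (config$planted_pairs == 0 || config$n_drugs == 0 || config$n_genes == 0) {
    return(tibble(drug_id = character(0), gene_symbol = character(0),
                  direction = character(0)))
  }
  p_up <- ceiling(config$planted_pairs / 2)
  p_down <- config$planted_pairs - p_up
  drug_perm <- sample(drugs, config$n_drugs)
  gene_perm <- sample(genes, config$n_genes)

  block <- function(p, offset_d, offset_g) {
    if (p == 0) {
      return(tibble(drug_id = character(0), gene_symbol = character(0)))
    }
    d <- min(config$n_drugs, max(1L, floor(sqrt(p))))
    g <- min(config$n_genes, ceiling(p / d))
    if (d * g < p) d <- min(config$n_drugs, ceiling(p / g))
    # disjoint drug/gene sets across directions when capacity allows
    di <- (offset_d + seq_len(d) - 1L) %% config$n_drugs + 1L
    gi <- (offset_g + seq_len(g) - 1L) %% config$n_genes + 1L
    tidyr::expand_grid(drug_id = drug_perm[di], gene_symbol = gene_perm[gi]) |>
      head(p)
  }
  up <- block(p_up, 0L, 0L)
  down <- block(p_down, dplyr::n_distinct(up$drug_id),
                dplyr::n_distinct(up$gene_symbol))
  bind_rows(
    up |> mutate(direction = "up"),
    down |> mutate(direction = "down")
  )
}

#' Ground-truth table of planted drug-gene regulations
#'
#' Reproduces exactly the planted (drug, gene, direction) triples used by
#' [gen_world()] for the same configuration, for use as ground truth in
#' recovery tests.
#'
#' @param config A [synth_config()].
#' @return A tibble with columns `drug_id`, `gene_symbol`, `direction`
#'   (values `"up"`/`"down"`), one row per planted pair.
#' @export
planted_truth <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed, plant_pairs(config))
}

#' Generate a synthetic chemogenomic world
#'
#' Draws every input table the pipeline consumes under a single seed.
#' Perturbation Z-scores are standard normal except for planted pairs, which
#' are shifted by `+effect_size` (up) or `-effect_size` (down) consistently
#' across all cell lines. A configurable fraction of records carry a "nM"
#' dose unit or a 6-h treatment time so the condition filters have work to
#' do. SMILES come from a built-in pool of valid drug-like structures. A
#' subset of CpG sites has histology-dependent intensity distributions so
#' methylation feature selection has real signal.
#'
#' @param config A [synth_config()].
#' @return A `gero_world` list of tibbles: `perturbations` (`drug_id`,
#'   `gene_symbol`, `cell_line`, `z_score`, `dose_value`, `dose_unit`,
#'   `time_h`), `smiles` (`drug_id`, `smiles`), `go_annotations`
#'   (`gene_symbol`, `go_term`), `mutations` (wide: `cell_line` + one 0/1
#'   column per marker), `intensities_meth` / `intensities_unmeth` (wide:
#'   `cell_line` + one column per CpG site; includes normal lines),
#'   `histology` (`cell_line`, `histology`; cancer lines only), `longevity`
#'   (`gene_symbol`, `label`), plus `normal_cells` and the `config`.
#' @export
gen_world <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed, {
    planted <- plant_pairs(config)
    drugs <- id_series("DRUG", config$n_drugs)
    genes <- id_series("GENE", config$n_genes)
    cells <- id_series("CL", config$n_cells)
    normal <- id_series("NORM", config$n_normal_cells)

    # perturbations: one record per drug x gene x cell
    if (config$n_drugs > 0 && config$n_genes > 0 && config$n_cells > 0) {
      pert <- tidyr::expand_grid(cell_line = cells, gene_symbol = genes,
                                 drug_id = drugs)
      n <- nrow(pert)
      shift <- planted$direction[match(
        paste(pert$drug_id, pert$gene_symbol),
        paste(planted$drug_id, planted$gene_symbol)
      )]
      z <- rnorm(n) +
        ifelse(is.na(shift), 0, ifelse(shift == "up", 1, -1) * config$effect_size)
      pert <- pert |>
        mutate(
          z_score = z,
          dose_value = sample(c(0.04, 0.12, 0.37, 1.11, 3.33, 10), n, replace = TRUE),
          dose_unit = ifelse(runif(n) < config$frac_alt_unit, "nM", "µM"),
          time_h = ifelse(runif(n) < config$frac_alt_time, 6, 24)
        ) |>
        select("drug_id", "gene_symbol", "cell_line", "z_score",
               "dose_value", "dose_unit", "time_h")
    } else {
      pert <- tibble(drug_id = character(0), gene_symbol = character(0),
                     cell_line = character(0), z_score = numeric(0),
                     dose_value = numeric(0), dose_unit = character(0),
                     time_h = numeric(0))
    }

    smiles <- tibble(drug_id = drugs, smiles = smiles_pool(config$n_drugs))

    # GO annotations: each term annotates a random 2-10 gene subset
    if (config$n_go_terms > 0 && config$n_genes > 0) {
      terms <- sprintf("GO:%07d", seq_len(config$n_go_terms))
      go <- purrr::map(terms, function(t) {
        size <- sample(2:min(10, config$n_genes), 1)
        tibble(gene_symbol = sample(genes, size), go_term = t)
      }) |>
        bind_rows() |>
        arrange(.data$gene_symbol, .data$go_term)
    } else {
      go <- tibble(gene_symbol = character(0), go_term = character(0))
    }

    # binary mutation markers for cancer lines
    markers <- id_series("MUT", config$n_mutation_markers)
    mut <- matrix(as.integer(runif(config$n_cells * config$n_mutation_markers) < 0.25),
                  nrow = config$n_cells, dimnames = list(cells, markers))
    mutations <- as_tibble(mut, rownames = "cell_line")

    # histology classes, round-robin over cancer lines
    hist_classes <- id_series("HIST", max(config$n_histology_classes, 1L))
    histology <- tibble(
      cell_line = cells,
      histology = rep(hist_classes, length.out = config$n_cells)
    )

    # intensities: informative sites track histology class, others do not;
    # normal lines draw from the uninformative regime
    sites <- id_series("cg", config$n_cpg_sites)
    all_lines <- c(cells, normal)
    n_inf <- floor_frac(config$frac_informative_cpg, config$n_cpg_sites)
    levels3 <- c(0.15, 0.5, 0.85)
    meth <- unmeth <- matrix(
      0, nrow = length(all_lines), ncol = config$n_cpg_sites,
      dimnames = list(all_lines, sites)
    )
    if (config$n_cpg_sites > 0 && length(all_lines) > 0) {
      class_of <- setNames(match(histology$histology, hist_classes), cells)
      for (j in seq_len(config$n_cpg_sites)) {
        base_level <- runif(1, 0.3, 0.7)
        for (i in seq_along(all_lines)) {
          ln <- all_lines[i]
          level <- if (j <= n_inf && ln %in% cells) {
            levels3[(class_of[[ln]] + j) %% 3 + 1]
          } else {
            base_level
          }
          meth[i, j] <- rgamma(1, shape = 50, rate = 50 / (level * 1000 + 1))
          unmeth[i, j] <- rgamma(1, shape = 50, rate = 50 / ((1 - level) * 1000 + 1))
        }
      }
    }
    intens_m <- as_tibble(meth, rownames = "cell_line")
    intens_u <- as_tibble(unmeth, rownames = "cell_line")

    # longevity labels: floor(frac * n_genes) per class
    n_pro <- floor_frac(config$frac_pro, config$n_genes)
    n_anti <- floor_frac(config$frac_anti, config$n_genes)
    perm <- sample(genes, config$n_genes)
    longevity <- tibble(
      gene_symbol = c(perm[seq_len(n_pro)],
                      perm[n_pro + seq_len(n_anti)]),
      label = c(rep("pro", n_pro), rep("anti", n_anti))
    ) |>
      arrange(.data$gene_symbol)

    structure(
      list(perturbations = pert, smiles = smiles, go_annotations = go,
           mutations = mutations, intensities_meth = intens_m,
           intensities_unmeth = intens_u, histology = histology,
           longevity = longevity, normal_cells = normal, config = config),
      class = "gero_world"
    )
  })
}

#' @export
print.gero_world <- function(x, ...) {
  cfg <- x$config
  cat("<gero_world> ", cfg$n_drugs, " drugs x ", cfg$n_genes, " genes x ",
      cfg$n_cells, " cell lines (", nrow(x$perturbations),
      " perturbation records, ", cfg$planted_pairs, " planted pairs, seed ",
      cfg$seed, ")\n", sep = "")
  invisible(x)
}

#' Write a synthetic world to plain-text files
#'
#' Writes `perturbations.tsv`, `smiles.csv`, `go_annotations.tsv`,
#' `mutations.csv`, `intensities_meth.csv`, `intensities_unmeth.csv`,
#' `histology.csv` and `longevity.csv` into `dir`.
#'
#' @param world A `gero_world` from [gen_world()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "gero_world"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(world$perturbations, file.path(dir, "perturbations.tsv"))
  readr::write_csv(world$smiles, file.path(dir, "smiles.csv"))
  readr::write_tsv(world$go_annotations, file.path(dir, "go_annotations.tsv"))
  readr::write_csv(world$mutations, file.path(dir, "mutations.csv"))
  readr::write_csv(world$intensities_meth, file.path(dir, "intensities_meth.csv"))
  readr::write_csv(world$intensities_unmeth, file.path(dir, "intensities_unmeth.csv"))
  readr::write_csv(world$histology, file.path(dir, "histology.csv"))
  readr::write_csv(world$longevity, file.path(dir, "longevity.csv"))
  invisible(dir)
}

#' Built-in pool of drug-like SMILES
#'
#' Returns `n` valid, diverse, neutral drug-like SMILES strings. The first 50
#' come from a hard-coded pool of well-known small molecules; beyond that the
#' pool is extended with an enumerated homologous series of N-alkyl
#' benzamides, which guarantees parseable, mutually distinct structures for
#' arbitrarily large worlds.
#'
#' @param n Number of SMILES to return.
#' @return Character vector of length `n`.
#' @export
smiles_pool <- function(n) {
  base <- .gerochem_smiles
  if (n <= length(base)) return(base[seq_len(n)])
  extra <- vapply(seq_len(n - length(base)), function(k) {
    paste0("O=C(N", strrep("C", k), ")c1ccccc1")
  }, character(1))
  c(base, extra)
}

# 50 neutral, valid drug-like structures (verified parseable with OpenBabel).
.gerochem_smiles <- c(
  "CC(=O)Oc1ccccc1C(=O)O",                       # aspirin
  "Cn1cnc2c1c(=O)n(C)c(=O)n2C",                  # caffeine
  "CC(C)Cc1ccc(cc1)C(C)C(=O)O",                  # ibuprofen
  "CC(=O)Nc1ccc(O)cc1",                          # paracetamol
  "COc1ccc2cc(ccc2c1)C(C)C(=O)O",                # naproxen
  "CN1CCCC1c1cccnc1",                            # nicotine
  "O=C(O)c1ccccc1O",                             # salicylic acid
  "CCOC(=O)c1ccc(N)cc1",                         # benzocaine
  "CCN(CC)CC(=O)Nc1c(C)cccc1C",                  # lidocaine
  "CCN(CC)CCOC(=O)c1ccc(N)cc1",                  # procaine
  "O=C1NC(=O)C(N1)(c1ccccc1)c1ccccc1",           # phenytoin
  "CCC(CO)NCCNC(CC)CO",                          # ethambutol
  "CN(C)C(=N)NC(=N)N",                           # metformin
  "CCCC(CCC)C(=O)O",                             # valproic acid
  "CC(=O)CC(c1ccccc1)c1c(O)c2ccccc2oc1=O",       # warfarin
  "CN1c2ccc(Cl)cc2C(=NCC1=O)c1ccccc1",           # diazepam
  "CNC1(c2ccccc2Cl)CCCCC1=O",                    # ketamine
  "CC(C)NCC(O)COc1cccc2ccccc12",                 # propranolol
  "CC(C)NCC(O)COc1ccc(CC(N)=O)cc1",              # atenolol
  "Cn1c(=O)c2[nH]cnc2n(C)c1=O",                  # theophylline
  "CN(C)CCCN1c2ccccc2Sc2ccc(Cl)cc21",            # chlorpromazine
  "CN(C)CCCN1c2ccccc2CCc2ccccc21",               # imipramine
  "CNCCC(Oc1ccc(cc1)C(F)(F)F)c1ccccc1",          # fluoxetine
  "Nc1ccc(cc1)S(N)(=O)=O",                       # sulfanilamide
  "CCC1(c2ccccc2)C(=O)NC(=O)NC1=O",              # phenobarbital
  "NNC(=O)c1ccncc1",                             # isoniazid
  "NC(=O)c1cnccn1",                              # pyrazinamide
  "CC(N)Cc1ccccc1",                              # amphetamine
  "CNC(C)C(O)c1ccccc1",                          # ephedrine
  "COc1cc(CCN)cc(OC)c1OC",                       # mescaline
  "NCCc1ccc(O)c(O)c1",                           # dopamine
  "NCCc1c[nH]c2ccc(O)cc12",                      # serotonin
  "CC(=O)NCCc1c[nH]c2ccc(OC)cc12",               # melatonin
  "NC(Cc1c[nH]c2ccccc12)C(=O)O",                 # tryptophan
  "NC(Cc1ccc(O)cc1)C(=O)O",                      # tyrosine
  "COc1ccc2c(c1)c(CC(=O)O)c(C)n2C(=O)c1ccc(Cl)cc1", # indomethacin
  "Oc1ccc2ccccc2c1",                             # 2-naphthol
  "CCN(CC)CCCC(C)Nc1ccnc2cc(Cl)ccc12",           # chloroquine
  "Cc1nc2ccccc2[nH]1",                           # 2-methylbenzimidazole
  "O=C1C=Cc2ccccc2O1",                           # coumarin
  "OC(=O)C=Cc1ccccc1",                           # cinnamic acid
  "CC(C)C1CCC(C)CC1O",                           # menthol
  "CC1(C)C2CCC1(C)C(=O)C2",                      # camphor
  "CC(=C)C1CC=C(C)CC1",                          # limonene
  "COc1cc(C=O)ccc1O",                            # vanillin
  "C=CCc1ccc(O)c(OC)c1",                         # eugenol
  "Oc1ccc(C=Cc2cc(O)cc(O)c2)cc1",                # resveratrol
  "Cc1ncc(N(=O)=O)n1CCO",                        # metronidazole
  "CN1C2CCC1CC(C2)OC(=O)C(CO)c1ccccc1",          # atropine
  "CC(CS)C(=O)N1CCCC1C(=O)O"                     # captopril
)
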