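# Morgan (circular, ECFP-style) fingerprints ----------------------------------
#
# Drug descriptors are binary vectors in which bit 1 means "some circular
# substructure of the molecule hashes to this position". SMILES are
# canonicalized and parsed with OpenBabel (via ChemmineOB/ChemmineR); the
# iterative neighborhood-hashing itself -- ECFP atom invariants, per-radius
# identifier updates, and deduplication of environments that cover the same
# bond set -- is implemented here and folded to a fixed bit length.

.element_numbers <- c(
  H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15, S = 16,
  Cl = 17, Se = 34, Br = 35, I = 53
)

# Deterministic integer-tuple hash: polynomial accumulation modulo the
# Mersenne prime 2^31 - 1. All intermediates stay exact in doubles.
hash_ints <- function(v) {
  h <- 17
  for (x in v) h <- (h * 31 + (x %% 2147483647)) %% 2147483647
  h
}

#' Canonicalize a SMILES string
#'
#' @param smiles A single SMILES string.
#' @return The OpenBabel canonical SMILES, or an error of class
#'   `gerochem_smiles_error` if the string cannot be parsed.
#' @export
canonical_smiles <- function(smiles) {
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", smiles),
    error = function(e) ""
  )
  out <- trimws(sub("\t.*$", "", out))
  if (!nzchar(out)) {
    abort(sprintf("SMILES could not be parsed: %s", smiles),
          class = "gerochem_smiles_error")
  }
  out
}

# Parse a SMILES into a heavy-atom molecular graph. Hydrogens are made
# explicit during conversion so per-atom H counts are read off the graph
# rather than inferred from valence rules.
parse_molecule <- function(smiles) {
  canon <- canonical_smiles(smiles)
  sdftxt <- tryCatch(
    ChemmineOB::convertFormat(
      "SMI", "SDF", canon,
      options = data.frame(names = c("h", "gen2d"), args = c("", ""))
    ),
    error = function(e) ""
  )
  if (!nzchar(sdftxt)) {
    abort(sprintf("SMILES could not be converted to a molecular graph: %s", smiles),
          class = "gerochem_smiles_error")
  }
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf), add = TRUE)
  writeLines(sdftxt, tf)
  sdf <- ChemmineR::read.SDFset(tf)[[1]]

  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  symbols <- sub("_.*$", "", rownames(ab))
  n_all <- length(symbols)
  charges <- numeric(n_all)
  chg_lines <- grep("^M  CHG", strsplit(sdftxt, "\n")[[1]], value = TRUE)
  for (ln in chg_lines) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG\\s+\\d+", "", ln)), "\\s+")[[1]])
    if (length(f) >= 2) {
      idx <- f[seq(1, length(f), by = 2)]
      val <- f[seq(2, length(f), by = 2)]
      charges[idx] <- val
    }
  }

  heavy <- which(symbols != "H")
  if (length(heavy) == 0) {
    abort(sprintf("molecule has no heavy atoms: %s", smiles),
          class = "gerochem_smiles_error")
  }
  heavy_pos <- match(seq_len(n_all), heavy)  # all-atom index -> heavy index

  a1 <- as.integer(bb[, 1]); a2 <- as.integer(bb[, 2]); ord <- as.integer(bb[, 3])
  h_count <- integer(length(heavy))
  keep <- symbols[a1] != "H" & symbols[a2] != "H"
  for (k in which(!keep)) {
    if (symbols[a1[k]] == "H" && symbols[a2[k]] != "H") {
      h_count[heavy_pos[a2[k]]] <- h_count[heavy_pos[a2[k]]] + 1L
    } else if (symbols[a2[k]] == "H" && symbols[a1[k]] != "H") {
      h_count[heavy_pos[a1[k]]] <- h_count[heavy_pos[a1[k]]] + 1L
    }
  }
  bonds <- tibble(
    a = heavy_pos[a1[keep]], b = heavy_pos[a2[keep]], order = ord[keep]
  )

  unknown <- setdiff(unique(symbols[heavy]), names(.element_numbers))
  if (length(unknown) > 0) {
    abort(sprintf("unsupported element(s) %s in SMILES: %s",
                  paste(unknown, collapse = ", "), smiles),
          class = "gerochem_smiles_error")
  }

  list(
    canonical = canon,
    symbol = symbols[heavy],
    atomic_number = unname(.element_numbers[symbols[heavy]]),
    charge = charges[heavy],
    h_count = h_count,
    bonds = bonds
  )
}

# An edge lies on a ring iff it is not a bridge of the heavy-atom graph.
ring_membership <- function(n_atoms, bonds) {
  in_ring_edge <- rep(FALSE, nrow(bonds))
  if (nrow(bonds) > 0) {
    g <- igraph::graph_from_edgelist(as.matrix(bonds[, c("a", "b")]),
                                     directed = FALSE)
    br <- igraph::bridges(g)
    in_ring_edge <- !(seq_len(nrow(bonds)) %in% as.integer(br))
  }
  in_ring_atom <- rep(FALSE, n_atoms)
  for (k in which(in_ring_edge)) {
    in_ring_atom[bonds$a[k]] <- TRUE
    in_ring_atom[bonds$b[k]] <- TRUE
  }
  list(edge = in_ring_edge, atom = in_ring_atom)
}

#' Morgan circular fingerprint of a molecule
#'
#' Computes a binary circular-substructure fingerprint: each atom starts
#' from an invariant of (atomic number, heavy degree, attached hydrogens,
#' formal charge, ring membership); identifiers are then iteratively updated
#' from each atom's bond-ordered neighborhood up to the given radius, with
#' environments that cover an already-seen bond set discarded, and all
#' surviving identifiers folded into `n_bits` positions. The SMILES is
#' canonicalized before hashing, so equivalent SMILES notations of the same
#' molecule give identical vectors.
#'
#' @param smiles A single SMILES string.
#' @param radius Neighborhood radius (default 2).
#' @param n_bits Folded fingerprint length (default 2048).
#' @return An integer 0/1 vector of length `n_bits`.
#' @export
#' @examples
#' fp <- morgan_fingerprint("CCO")
#' length(fp)
#' sum(fp)
morgan_fingerprint <- function(smiles, radius = 2, n_bits = 2048) {
  mol <- parse_molecule(smiles)
  n <- length(mol$symbol)
  bonds <- mol$bonds
  rings <- ring_membership(n, bonds)

  nb <- vector("list", n)          # per atom: matrix cols (neighbor, order, edge)
  for (i in seq_len(n)) nb[[i]] <- matrix(integer(0), ncol = 3)
  if (nrow(bonds) > 0) {
    for (k in seq_len(nrow(bonds))) {
      nb[[bonds$a[k]]] <- rbind(nb[[bonds$a[k]]], c(bonds$b[k], bonds$order[k], k))
      nb[[bonds$b[k]]] <- rbind(nb[[bonds$b[k]]], c(bonds$a[k], bonds$order[k], k))
    }
  }

  ids <- vapply(seq_len(n), function(i) {
    hash_ints(c(mol$atomic_number[i], nrow(nb[[i]]), mol$h_count[i],
                mol$charge[i], as.integer(rings$atom[i])))
  }, numeric(1))
  all_ids <- ids
  bondsets <- replicate(n, integer(0), simplify = FALSE)
  seen_sets <- character(0)

  if (radius >= 1) {
    for (r in seq_len(radius)) {
      new_ids <- ids
      new_sets <- bondsets
      has_nb <- vapply(seq_len(n), function(i) nrow(nb[[i]]) > 0, logical(1))
      for (i in which(has_nb)) {
        pairs <- cbind(nb[[i]][, 2], ids[nb[[i]][, 1]])
        pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
        new_ids[i] <- hash_ints(c(r, ids[i], t(pairs)))
        new_sets[[i]] <- sort(unique(c(
          bondsets[[i]], unlist(bondsets[nb[[i]][, 1]]), nb[[i]][, 3]
        )))
      }
      cand <- which(has_nb)
      for (i in cand[order(new_ids[cand])]) {
        key <- paste(new_sets[[i]], collapse = ",")
        if (!(key %in% seen_sets)) {
          seen_sets <- c(seen_sets, key)
          all_ids <- c(all_ids, new_ids[i])
        }
      }
      ids <- new_ids
      bondsets <- new_sets
    }
  }

  fp <- integer(n_bits)
  fp[unique(all_ids %% n_bits) + 1] <- 1L
  fp
}

#' Fingerprint a table of drugs
#'
#' Applies [morgan_fingerprint()] to every drug in a SMILES table. Drugs
#' whose SMILES cannot be parsed are collected in a failure table (and should
#' be excluded downstream) rather than aborting the run.
#'
#' @param smiles_tbl Tibble with columns `drug_id`, `smiles`.
#' @param radius,n_bits Passed to [morgan_fingerprint()].
#' @return A list with `matrix` (drugs x bits, rownames = drug ids, colnames
#'   `bit0001`...) and `failures` (tibble `drug_id`, `message`).
#' @export
fingerprint_drugs <- function(smiles_tbl, radius = 2, n_bits = 2048) {
  assert_columns(smiles_tbl, c("drug_id", "smiles"), "SMILES table")
  res <- purrr::map(smiles_tbl$smiles, function(s) {
    tryCatch(list(fp = morgan_fingerprint(s, radius, n_bits), err = NA_character_),
             gerochem_smiles_error = function(e) list(fp = NULL, err = conditionMessage(e)))
  })
  ok <- vapply(res, function(x) is.null(x$err) || is.na(x$err), logical(1))
  mat <- matrix(0L, nrow = sum(ok), ncol = n_bits,
                dimnames = list(smiles_tbl$drug_id[ok],
                                sprintf("bit%04d", seq_len(n_bits))))
  if (any(ok)) {
    mat[] <- do.call(rbind, lapply(res[ok], `[[`, "fp"))
  }
  failures <- tibble(
    drug_id = smiles_tbl$drug_id[!ok],
    message = vapply(res[!ok], `[[`, character(1), "err")
  )
  if (nrow(failures) > 0) {
    inform(sprintf("%d drug(s) failed fingerprinting and will be excluded: %s",
                   nrow(failures), paste(failures$drug_id, collapse = ", ")))
  }
  list(matrix = mat, failures = failures)
}
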