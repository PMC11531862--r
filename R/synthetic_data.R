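# Synthetic desk-scale datasets with the statistical structure the model
# assumes: self-avoiding 3D backbones with fixed consecutive-Ca spacing,
# per-residue Gaussian embeddings carrying contiguous motif signals, GO
# labels determined by motif presence, and localization labels that are
# noisy boolean functions of the GO labels.

#' Default motif catalogue
#'
#' One row per GO term: ontology, motif length `k`, embedding shift
#' magnitude `mu`, and prevalence.  8 BP, 5 CC and 5 MF terms.
#'
#' @param k Motif length (residues).
#' @param mu Embedding shift magnitude along the term's direction vector.
#' @param prevalence Probability a protein carries the term's motif.
#' @return data.frame with columns term, ontology, k, mu, prevalence.
#' @export
default_motif_catalogue <- function(k = 8L, mu = 1.5, prevalence = 0.3) {
  terms <- c(paste0("bp", 1:8), paste0("cc", 1:5), paste0("mf", 1:5))
  data.frame(
    term = terms,
    ontology = c(rep("BP", 8), rep("CC", 5), rep("MF", 5)),
    k = as.integer(k), mu = mu, prevalence = prevalence,
    stringsAsFactors = FALSE
  )
}

#' Default localization rule table
#'
#' Each localization class is a small OR-of-ANDs boolean formula over GO
#' terms, encoding the premise that localization is driven by function.
#'
#' @return Named list; each element is a list of character vectors (clauses
#'   are ANDed within a vector, ORed across vectors).
#' @export
default_sl_rules <- function() {
  list(
    sl1 = list("bp1", "bp2"),
    sl2 = list("cc1", "mf1"),
    sl3 = list(c("bp3", "cc2"), "mf3"),
    sl4 = list("mf2", "cc3")
  )
}

#' Simulation configuration
#'
#' @param n_proteins Number of proteins.
#' @param len_range Length range (inclusive) for sequences.
#' @param d_h Embedding dimension.
#' @param bond_length Consecutive-Ca spacing in Angstroms (default 3.8,
#'   the trans-peptide Ca-Ca distance; below the 4.5 A contact threshold so
#'   chains stay connected).
#' @param exclusion_radius Excluded-volume radius in Angstroms: no two
#'   non-consecutive residues may come closer than this (default 3.6).
#' @param catalogue Motif catalogue (see [default_motif_catalogue()]).
#' @param sl_rules Localization rule table (see [default_sl_rules()]).
#' @param noise_rate Independent flip probability for each localization
#'   label, in [0, 0.5).
#' @param seed Master seed; per-protein seeds are derived from it.
#' @return Object of class `sim_config` (includes per-term unit direction
#'   vectors drawn under the seed).
#' @export
sim_config <- function(n_proteins = 300L, len_range = c(30L, 60L), d_h = 16L,
                       bond_length = 3.8, exclusion_radius = 3.6,
                       catalogue = default_motif_catalogue(),
                       sl_rules = default_sl_rules(),
                       noise_rate = 0.05, seed = 1L) {
  stopifnot(noise_rate >= 0, noise_rate < 0.5,
            all(catalogue$prevalence > 0), all(catalogue$prevalence < 1),
            exclusion_radius > 0, bond_length > 0, nrow(catalogue) > 0)
  dirs <- with_seed(seed * 31L + 7L, {
    m <- matrix(stats::rnorm(nrow(catalogue) * d_h), nrow(catalogue), d_h)
    m / sqrt(rowSums(m * m))
  })
  rownames(dirs) <- catalogue$term
  structure(
    list(n_proteins = as.integer(n_proteins),
         len_range = as.integer(len_range), d_h = as.integer(d_h),
         bond_length = bond_length, exclusion_radius = exclusion_radius,
         catalogue = catalogue, sl_rules = sl_rules,
         noise_rate = noise_rate, seed = as.integer(seed),
         motif_dirs = dirs),
    class = "sim_config"
  )
}

#' Generate a self-avoiding random-walk backbone
#'
#' Fixed-step random walk: each Ca is placed at `bond_length` from its
#' predecessor in a uniformly random direction; proposals closer than the
#' exclusion radius to any earlier residue are rejected (up to 100 retries
#' per step, then the chain restarts, up to 20 restarts).
#'
#' @param L Number of residues.
#' @param config A `sim_config` (bond length and exclusion radius).
#' @param seed Seed.
#' @return L x 3 coordinate matrix.
#' @export
generate_backbone <- function(L, config = sim_config(), seed = 1L) {
  stopifnot(L >= 1L)
  b <- config$bond_length
  excl <- config$exclusion_radius
  with_seed(seed, {
    for (restart in seq_len(20L)) {
      coords <- matrix(0, L, 3L)
      ok <- TRUE
      for (i in seq_len(L)[-1L]) {
        placed <- FALSE
        for (try in seq_len(100L)) {
          u <- stats::rnorm(3L)
          u <- u / sqrt(sum(u * u))
          prop <- coords[i - 1L, ] + b * u
          prior <- coords[seq_len(i - 2L), , drop = FALSE]
          if (nrow(prior) > 0L) {
            d2 <- rowSums(sweep(prior, 2L, prop)^2)
            if (min(d2) < excl^2) next
          }
          coords[i, ] <- prop
          placed <- TRUE
          break
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (ok) return(coords)
    }
    stop("backbone generation failed: persistent self-collision", call. = FALSE)
  })
}

# evaluate an OR-of-ANDs rule on a named 0/1 GO vector
.eval_rule <- function(clauses, go) {
  for (cl in clauses) {
    if (all(go[cl] == 1)) return(1)
  }
  0
}

#' Generate one synthetic protein
#'
#' Embeddings are i.i.d. standard normal; for each catalogue term drawn
#' present (per prevalence), a random contiguous window of `k` residues has
#' its embedding rows shifted by `mu` along the term's direction vector.
#' GO labels record motif presence; localization labels evaluate the rule
#' table on the GO labels and are flipped independently with probability
#' `noise_rate`.
#'
#' @param config A `sim_config`.
#' @param seed Seed for this protein.
#' @param id Protein identifier.
#' @return A protein record: list(id, sequence, coords, embedding, go_bp,
#'   go_cc, go_mf, sl, motif_windows).
#' @export
generate_protein <- function(config, seed = 1L, id = "p1") {
  cat_tab <- config$catalogue
  lens <- seq.int(config$len_range[1], config$len_range[2])
  L <- with_seed(seed * 3L + 11L, lens[sample.int(length(lens), 1L)])
  coords <- generate_backbone(L, config, seed = seed * 3L + 12L)
  with_seed(seed * 3L + 13L, {
    sequence <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                             L, replace = TRUE), collapse = "")
    emb <- matrix(stats::rnorm(L * config$d_h), L, config$d_h)
    go <- stats::setNames(numeric(nrow(cat_tab)), cat_tab$term)
    windows <- list()
    for (r in seq_len(nrow(cat_tab))) {
      term <- cat_tab$term[r]
      if (stats::runif(1) >= cat_tab$prevalence[r]) next
      k <- cat_tab$k[r]
      if (k > L) {
        warning("motif ", term, " (k=", k, ") longer than protein ", id,
                " (L=", L, "); term skipped", call. = FALSE)
        next
      }
      start <- sample.int(L - k + 1L, 1L)
      win <- start:(start + k - 1L)
      emb[win, ] <- emb[win, ] +
        rep(cat_tab$mu[r] * config$motif_dirs[term, ], each = k)
      go[term] <- 1
      windows[[term]] <- win
    }
    sl <- vapply(config$sl_rules, .eval_rule, numeric(1), go = go)
    flips <- stats::runif(length(sl)) < config$noise_rate
    sl <- abs(sl - as.numeric(flips))
    onto <- cat_tab$ontology
    list(id = id, sequence = sequence, coords = coords, embedding = emb,
         go_bp = unname(go[onto == "BP"]), go_cc = unname(go[onto == "CC"]),
         go_mf = unname(go[onto == "MF"]), sl = unname(sl),
         motif_windows = windows)
  })
}

#' Generate a set of synthetic protein records in memory
#'
#' @param config A `sim_config`.
#' @return List of protein records (see [generate_protein()]).
#' @export
generate_records <- function(config) {
  lapply(seq_len(config$n_proteins), function(i) {
    generate_protein(config, seed = config$seed * 1009L + i,
                     id = sprintf("prot%04d", i))
  })
}

#' Generate a synthetic dataset directory
#'
#' Writes the layout expected by the readers: `sequences.fasta`,
#' `coords/<id>.xyz`, `embeddings/<id>.tsv`, `labels_{bp,cc,mf,sl}.tsv`
#' and a `manifest.json` recording the configuration and seed.
#'
#' @param config A `sim_config`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the list of generated records.
#' @export
generate_dataset <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "coords"), showWarnings = FALSE)
  dir.create(file.path(dir, "embeddings"), showWarnings = FALSE)
  records <- generate_records(config)
  seqs <- stats::setNames(lapply(records, `[[`, "sequence"),
                          vapply(records, `[[`, "", "id"))
  write_fasta(seqs, file.path(dir, "sequences.fasta"))
  onto <- config$catalogue$ontology
  terms <- list(bp = config$catalogue$term[onto == "BP"],
                cc = config$catalogue$term[onto == "CC"],
                mf = config$catalogue$term[onto == "MF"],
                sl = names(config$sl_rules))
  lab_rows <- list(bp = NULL, cc = NULL, mf = NULL, sl = NULL)
  for (r in records) {
    utils::write.table(r$coords, file.path(dir, "coords",
                                           paste0(r$id, ".xyz")),
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(round(r$embedding, 6),
                       file.path(dir, "embeddings", paste0(r$id, ".tsv")),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
    vecs <- list(bp = r$go_bp, cc = r$go_cc, mf = r$go_mf, sl = r$sl)
    for (t in names(vecs)) {
      on_terms <- terms[[t]][vecs[[t]] == 1]
      if (length(on_terms)) {
        lab_rows[[t]] <- rbind(lab_rows[[t]],
                               data.frame(protein_id = r$id, term = on_terms))
      }
    }
  }
  for (t in names(lab_rows)) {
    tab <- lab_rows[[t]]
    if (is.null(tab)) tab <- data.frame(protein_id = character(0),
                                        term = character(0))
    write_labels(tab, file.path(dir, paste0("labels_", t, ".tsv")))
  }
  manifest <- config
  manifest$motif_dirs <- NULL
  manifest$catalogue <- as.list(config$catalogue)
  jsonlite::write_json(unclass(manifest), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(records)
}

#' Load a dataset directory written by [generate_dataset()]
#'
#' @param dir Dataset directory.
#' @param vocab Named list of term vectors (bp, cc, mf, sl); read from the
#'   manifest when NULL.
#' @return List of protein records suitable for [prepare_dataset()].
#' @export
load_dataset <- function(dir, vocab = NULL) {
  seqs <- read_fasta(file.path(dir, "sequences.fasta"))
  if (is.null(vocab)) {
    man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                               simplifyVector = TRUE)
    onto <- man$catalogue$ontology
    vocab <- list(bp = man$catalogue$term[onto == "BP"],
                  cc = man$catalogue$term[onto == "CC"],
                  mf = man$catalogue$term[onto == "MF"],
                  sl = names(man$sl_rules))
  }
  labs <- lapply(c(bp = "bp", cc = "cc", mf = "mf", sl = "sl"), function(t) {
    read_labels(file.path(dir, paste0("labels_", t, ".tsv")))
  })
  lapply(names(seqs), function(id) {
    coords <- read_coords(file.path(dir, "coords", paste0(id, ".xyz")))
    emb <- as.matrix(utils::read.table(
      file.path(dir, "embeddings", paste0(id, ".tsv")), sep = "\t"))
    dimnames(emb) <- NULL
    onehot <- function(t) {
      as.numeric(vocab[[t]] %in% labs[[t]]$term[labs[[t]]$protein_id == id])
    }
    list(id = id, sequence = seqs[[id]], coords = coords, embedding = emb,
         go_bp = onehot("bp"), go_cc = onehot("cc"), go_mf = onehot("mf"),
         sl = onehot("sl"))
  })
}
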