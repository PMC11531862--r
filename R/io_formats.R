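#' Read a FASTA file of protein sequences
#'
#' A small validating parser: every record must have a non-empty header line
#' starting with `>` and at least one non-empty sequence line.  Sequence
#' lines may be wrapped; they are re-joined and uppercased.  Malformed input
#' raises an error naming the offending line so batch ingestion failures are
#' actionable.
#'
#' @param path Path to a FASTA file.
#' @return A named list of sequences (names are the first whitespace-delimited
#'   token of each header), in file order.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  ids <- character(0)
  seqs <- character(0)
  cur_id <- NULL
  cur_seq <- character(0)
  flush_record <- function(at_line) {
    if (is.null(cur_id)) return()
    s <- paste(cur_seq, collapse = "")
    if (!nzchar(s)) {
      stop("empty FASTA record '", cur_id, "' ending at line ", at_line,
           call. = FALSE)
    }
    ids <<- c(ids, cur_id)
    seqs <<- c(seqs, toupper(s))
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, ">")) {
      flush_record(i - 1L)
      hdr <- trimws(sub("^>", "", ln))
      if (!nzchar(hdr)) stop("malformed FASTA header at line ", i, call. = FALSE)
      cur_id <- strsplit(hdr, "\\s+")[[1]][1]
      cur_seq <- character(0)
    } else if (nzchar(trimws(ln))) {
      if (is.null(cur_id)) {
        stop("sequence data before any FASTA header at line ", i, call. = FALSE)
      }
      sq <- gsub("\\s", "", ln)
      if (grepl("[^A-Za-z*-]", sq)) {
        stop("invalid sequence characters at line ", i, call. = FALSE)
      }
      cur_seq <- c(cur_seq, sq)
    }
  }
  flush_record(length(lines))
  stats::setNames(as.list(seqs), ids)
}

#' Write sequences to FASTA
#'
#' @param seqs Named list or character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read alpha-carbon coordinates
#'
#' Accepts a PDB or mmCIF structure (one Ca per residue is extracted from the
#' first chain, in chain order, via \pkg{bio3d}) or a plain whitespace-
#' delimited table with three numeric columns (x, y, z in Angstroms, one row
#' per residue).  Multi-chain structures are reduced to the first chain; the
#' upstream structure provider is expected to supply single-chain models.
#'
#' @param path Path to a `.pdb`, `.cif` or plain xyz table.
#' @return An n x 3 numeric matrix of Ca positions in Angstroms.
#' @export
read_coords <- function(path) {
  stopifnot(file.exists(path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("pdb", "ent")) {
    return(.coords_from_bio3d(bio3d::read.pdb(path, verbose = FALSE), path))
  }
  if (ext %in% c("cif", "mmcif")) {
    return(.coords_from_bio3d(bio3d::read.cif(path, verbose = FALSE), path))
  }
  tab <- tryCatch(
    utils::read.table(path, header = FALSE, comment.char = "#"),
    error = function(e) stop("cannot parse coordinate table '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (ncol(tab) != 3L || !all(vapply(tab, is.numeric, TRUE))) {
    stop("xyz coordinate table must have exactly 3 numeric columns: ", path,
         call. = FALSE)
  }
  m <- as.matrix(tab)
  dimnames(m) <- NULL
  if (!all(is.finite(m))) stop("non-finite coordinates in ", path, call. = FALSE)
  m
}

.coords_from_bio3d <- function(pdb, path) {
  sel <- bio3d::atom.select(pdb, elety = "CA", verbose = FALSE)
  if (length(sel$atom) == 0L) {
    stop("no Ca atoms found in structure file ", path, call. = FALSE)
  }
  at <- pdb$atom[sel$atom, , drop = FALSE]
  ch <- at$chain[1]
  at <- at[at$chain %in% ch | is.na(at$chain), , drop = FALSE]
  m <- as.matrix(at[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

#' Read a protein-to-term label table
#'
#' @param path TSV with two columns: protein_id, term (no header or a header
#'   line `protein_id	term`).
#' @return A data.frame with columns `protein_id` and `term`.
#' @export
read_labels <- function(path) {
  stopifnot(file.exists(path))
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           col.names = c("protein_id", "term"),
                           colClasses = "character", quote = "")
  if (nrow(tab) > 0L && identical(tolower(tab$protein_id[1]), "protein_id")) {
    tab <- tab[-1L, , drop = FALSE]
  }
  rownames(tab) <- NULL
  tab
}

#' Write a protein-to-term label table
#' @param labels data.frame with columns protein_id, term.
#' @param path Output TSV path.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(labels[, c("protein_id", "term")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Build a label vocabulary with a frequency filter
#'
#' Terms annotated on at least `min_frequency` distinct proteins are retained
#' and sorted lexicographically, fixing the column order of score and label
#' matrices across runs.  Proteins whose annotations are entirely filtered
#' out are reported in the `orphaned` attribute (they are flagged, not
#' silently dropped).
#'
#' @param label_table data.frame with columns protein_id, term.
#' @param ontology One of "BP", "CC", "MF", "SL".
#' @param min_frequency Minimum number of distinct proteins per retained term.
#' @return An object of class `label_vocabulary`: list(ontology, terms,
#'   min_frequency), with attribute `orphaned`.
#' @export
build_vocabulary <- function(label_table, ontology = "BP", min_frequency = 20L) {
  stopifnot(min_frequency >= 1L)
  if (nrow(label_table) == 0L) stop("empty label table", call. = FALSE)
  uniq <- unique(label_table[, c("protein_id", "term")])
  counts <- table(uniq$term)
  keep <- sort(names(counts)[counts >= min_frequency])
  kept_prot <- unique(uniq$protein_id[uniq$term %in% keep])
  orphaned <- setdiff(unique(uniq$protein_id), kept_prot)
  vocab <- structure(
    list(ontology = ontology, terms = keep,
         min_frequency = as.integer(min_frequency)),
    class = "label_vocabulary"
  )
  attr(vocab, "orphaned") <- orphaned
  if (length(orphaned) > 0L) {
    warning(length(orphaned), " protein(s) lost all ", ontology,
            " annotations under the frequency filter", call. = FALSE)
  }
  vocab
}

#' Convert a label table to a binary matrix over a vocabulary
#'
#' @param label_table data.frame with columns protein_id, term.
#' @param protein_ids Row order.
#' @param vocab A `label_vocabulary`.
#' @return Binary matrix, rows = proteins, columns = vocabulary terms.
#' @export
labels_to_matrix <- function(label_table, protein_ids, vocab) {
  m <- matrix(0, length(protein_ids), length(vocab$terms),
              dimnames = list(protein_ids, vocab$terms))
  tab <- label_table[label_table$term %in% vocab$terms &
                       label_table$protein_id %in% protein_ids, , drop = FALSE]
  if (nrow(tab) > 0L) m[cbind(tab$protein_id, tab$term)] <- 1
  m
}

#' Split a dataset into train/validation/test partitions
#'
#' Sizes are floor-allocated per fraction with the remainder assigned to the
#' training partition; membership is a seeded random permutation, so the
#' split is reproducible, disjoint and exhaustive.
#'
#' @param ids Vector of record identifiers (or any vector to split).
#' @param fractions Length-3 numeric summing to 1 (train, valid, test).
#' @param seed Integer seed.
#' @return list(train =, valid =, test =) of disjoint subsets of `ids`.
#' @export
split_dataset <- function(ids, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must be three numbers summing to 1", call. = FALSE)
  }
  n <- length(ids)
  stopifnot(n >= 3L)
  n_valid <- floor(fractions[2] * n)
  n_test <- floor(fractions[3] * n)
  n_train <- n - n_valid - n_test
  perm <- with_seed(seed, sample.int(n))
  list(
    train = ids[perm[seq_len(n_train)]],
    valid = ids[perm[n_train + seq_len(n_valid)]],
    test = ids[perm[n_train + n_valid + seq_len(n_test)]]
  )
}

#' Write per-protein prediction scores as TSV
#'
#' Columns: protein_id, task, term, score (6 decimal places).  Rows ordered
#' by protein, then task, then term, so output is deterministic.
#'
#' @param bundle Named list: per protein, a named list of score vectors per
#'   task; each score vector is named by term.  See [predict_proteins()].
#' @param path Output path.
#' @export
write_predictions <- function(bundle, path) {
  rows <- list()
  for (pid in names(bundle)) {
    tasks <- bundle[[pid]]
    for (task in names(tasks)) {
      sc <- tasks[[task]]
      if (is.null(names(sc))) {
        stop("score vector for ", pid, "/", task, " must be term-named",
             call. = FALSE)
      }
      if (any(sc < 0 | sc > 1)) {
        stop("scores outside [0,1] for ", pid, "/", task, call. = FALSE)
      }
      ord <- order(names(sc))
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = pid, task = task, term = names(sc)[ord],
        score = sprintf("%.6f", unname(sc)[ord]),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$protein_id, out$task, out$term), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a prediction TSV written by [write_predictions()]
#' @param path Path to the TSV.
#' @return Nested named list, same shape as the `bundle` argument of
#'   [write_predictions()].
#' @export
read_predictions <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = c("character", "character",
                                          "character", "numeric"))
  out <- list()
  for (pid in unique(tab$protein_id)) {
    sub <- tab[tab$protein_id == pid, , drop = FALSE]
    out[[pid]] <- lapply(split(sub, sub$task), function(s) {
      stats::setNames(s$score, s$term)
    })
  }
  out
}

#' Align a sequence with its coordinate table
#'
#' Length mismatches are resolved by trimming both to the shorter length,
#' with a warning; this mirrors the truncation stance taken for embedding
#' matrices.
#'
#' @param sequence Amino-acid string.
#' @param coords n x 3 matrix.
#' @return list(sequence =, coords =) of equal length.
#' @export
align_sequence_coords <- function(sequence, coords) {
  L <- nchar(sequence)
  n <- nrow(coords)
  if (L != n) {
    warning("sequence length ", L, " != coordinate rows ", n,
            "; trimming to ", min(L, n), call. = FALSE)
    k <- min(L, n)
    sequence <- substr(sequence, 1L, k)
    coords <- coords[seq_len(k), , drop = FALSE]
  }
  list(sequence = sequence, coords = coords)
}
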