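#' Read a count matrix and sample sheet into an experiment
#'
#' The counts TSV carries gene ids in its first column and sample ids in
#' the header; the sheet TSV maps every sample column to group, time and
#' replicate. Columns without a sheet entry are a hard error naming the
#' column, as is any non-integer count.
#'
#' @param counts_path path to the counts TSV.
#' @param sheet_path path to the sample-sheet TSV (columns sample_id,
#'   group, time_min, replicate).
#' @param genes_path optional TSV with gene_id and tf_family columns.
#' @return A [wound_experiment()].
#' @export
read_counts <- function(counts_path, sheet_path, genes_path = NULL) {
  cts <- readr::read_tsv(counts_path, show_col_types = FALSE, progress = FALSE)
  if (ncol(cts) < 2) abort("Counts TSV needs a gene column plus sample columns.")
  gene_ids <- as.character(cts[[1]])
  m <- as.matrix(cts[, -1, drop = FALSE])
  bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("Non-integer or negative count at gene '%s', column '%s'.",
                  gene_ids[bad[1, 1]], colnames(m)[bad[1, 2]]))
  }
  rownames(m) <- gene_ids
  sheet <- readr::read_tsv(sheet_path, show_col_types = FALSE, progress = FALSE)
  genes <- if (!is.null(genes_path)) {
    readr::read_tsv(genes_path, show_col_types = FALSE, progress = FALSE)
  }
  wound_experiment(m, sheet, genes = genes)
}

#' Write an experiment's counts and sample sheet
#'
#' @param experiment a [wound_experiment()].
#' @param counts_path,sheet_path output TSV paths.
#' @return `experiment`, invisibly.
#' @export
write_counts <- function(experiment, counts_path, sheet_path) {
  out <- as_tibble(experiment$counts, rownames = "gene_id")
  readr::write_tsv(out, counts_path, progress = FALSE)
  readr::write_tsv(experiment$samples, sheet_path, progress = FALSE)
  invisible(experiment)
}

#' Read gene-set annotation in GMT format
#'
#' One set per line: term id, description, then member genes, tab-separated.
#'
#' @param path path to the GMT file.
#' @return Named list of character vectors (unique gene ids per term), with
#'   a `description` attribute vector.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); descs <- character()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      abort(sprintf("Malformed GMT record at line %d: need term, description and >=1 gene.", i))
    }
    term <- parts[[1]]
    if (term %in% names(sets)) {
      abort(sprintf("Duplicate term '%s' at line %d.", term, i))
    }
    sets[[term]] <- unique(parts[-(1:2)])
    descs[[term]] <- parts[[2]]
  }
  attr(sets, "description") <- descs
  sets
}

#' Write gene sets as GMT
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional named descriptions (defaults to the term id).
#' @return `sets`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) {
    descriptions <- attr(sets, "description") %||% setNames(names(sets), names(sets))
  }
  lines <- vapply(names(sets), function(term) {
    paste(c(term, descriptions[[term]] %||% term, sets[[term]]), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(sets)
}

#' Read promoter sequences from FASTA
#'
#' @param path FASTA file of upstream promoter sequences.
#' @return Named character vector of uppercase sequences, one per gene.
#' @export
read_promoters <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    abort(paste0("Duplicate FASTA id(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  setNames(toupper(as.character(seqs)), ids)
}

#' Write promoter sequences as FASTA
#' @param promoters named character vector of sequences.
#' @param path output path.
#' @return `promoters`, invisibly.
#' @export
write_promoters <- function(promoters, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(promoters), path, width = 80L
  )
  invisible(promoters)
}

#' Read position weight matrices in MEME minimal motif format
#'
#' Parses `MOTIF` blocks with `letter-probability matrix` sections over the
#' alphabet ACGT. Each column (motif position) is renormalized to sum to 1,
#' tolerating the rounded probabilities MEME files carry.
#'
#' @param path MEME minimal format file.
#' @return Named list of `wound_pwm` objects (4 x width probability
#'   matrices, rows A, C, G, T).
#' @export
read_meme_pwm <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  pwms <- list()
  i <- 1
  while (i <= length(lines)) {
    ln <- trimws(lines[[i]])
    if (startsWith(ln, "MOTIF")) {
      name <- strsplit(ln, "\\s+")[[1]][2]
      if (is.na(name)) abort(sprintf("MOTIF without a name at line %d.", i))
      # seek the letter-probability header
      j <- i + 1
      while (j <= length(lines) &&
             !grepl("^letter-probability matrix", trimws(lines[[j]]))) {
        if (startsWith(trimws(lines[[j]]), "MOTIF")) {
          abort(sprintf("Motif '%s' has no letter-probability matrix (line %d).", name, i))
        }
        j <- j + 1
      }
      if (j > length(lines)) {
        abort(sprintf("Motif '%s' has no letter-probability matrix (line %d).", name, i))
      }
      rows <- list()
      j <- j + 1
      while (j <= length(lines)) {
        ln2 <- trimws(lines[[j]])
        if (!nzchar(ln2) || !grepl("^[0-9.eE+-]", ln2)) break
        vals <- suppressWarnings(as.numeric(strsplit(ln2, "\\s+")[[1]]))
        if (length(vals) != 4 || anyNA(vals)) {
          abort(sprintf("Malformed probability row at line %d (expect 4 numbers).", j))
        }
        rows[[length(rows) + 1]] <- vals
        j <- j + 1
      }
      if (length(rows) == 0) {
        abort(sprintf("Motif '%s': empty probability matrix (line %d).", name, i))
      }
      mat <- t(do.call(rbind, rows))        # 4 x width, rows A C G T
      rownames(mat) <- c("A", "C", "G", "T")
      mat <- sweep(mat, 2, colSums(mat), "/")
      pwms[[name]] <- new_pwm(mat, name = name)
      i <- j
    } else {
      i <- i + 1
    }
  }
  if (length(pwms) == 0) abort("No MOTIF records found.")
  pwms
}

#' Write PWMs in MEME minimal motif format
#' @param pwms named list of `wound_pwm` objects or 4 x width matrices.
#' @param path output path.
#' @return `pwms`, invisibly.
#' @export
write_meme_pwm <- function(pwms, path) {
  out <- c("MEME version 4", "", "ALPHABET= ACGT", "",
           "strands: + -", "",
           "Background letter frequencies",
           "A 0.25 C 0.25 G 0.25 T 0.25", "")
  for (name in names(pwms)) {
    m <- unclass(pwms[[name]])
    out <- c(out,
             paste("MOTIF", name),
             sprintf("letter-probability matrix: alength= 4 w= %d", ncol(m)),
             apply(m, 2, function(col) paste(sprintf("%.6f", col), collapse = " ")),
             "")
  }
  readr::write_lines(out, path)
  invisible(pwms)
}

new_pwm <- function(mat, name, background = rep(0.25, 4)) {
  stopifnot(nrow(mat) == 4, all(mat >= 0))
  if (any(abs(colSums(mat) - 1) > 1e-6)) {
    abort("PWM columns must sum to 1 after renormalization.")
  }
  structure(mat, name = name, background = background, class = "wound_pwm")
}

#' @export
print.wound_pwm <- function(x, ...) {
  cat(sprintf("<wound_pwm> %s, width %d, consensus %s\n",
              attr(x, "name"), ncol(x), pwm_consensus(x)))
  invisible(x)
}

#' Consensus sequence of a PWM (most probable base per position)
#' @param pwm a `wound_pwm`.
#' @return Character scalar.
#' @export
pwm_consensus <- function(pwm) {
  paste(rownames(pwm)[apply(unclass(pwm), 2, which.max)], collapse = "")
}

#' Read a volatile (trait) table
#'
#' Wide TSV, metabolites in rows and time points (minutes) in columns;
#' returned long and log-scaled downstream analyses expect raw peak areas
#' here.
#'
#' @param path trait TSV: first column metabolite id, remaining columns
#'   named by time in minutes.
#' @return Long tibble: metabolite, time_min, value.
#' @export
read_trait_table <- function(path) {
  wide <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(wide) < 2) abort("Trait TSV needs a metabolite column plus time columns.")
  names(wide)[1] <- "metabolite"
  if (anyDuplicated(wide$metabolite)) abort("Duplicate metabolite ids in trait table.")
  times <- suppressWarnings(as.numeric(names(wide)[-1]))
  if (anyNA(times)) {
    abort(paste0("Trait column name(s) not numeric minutes: ",
                 paste(names(wide)[-1][is.na(times)], collapse = ", ")))
  }
  long <- tidyr::pivot_longer(wide, -"metabolite",
                              names_to = "time_min", values_to = "value")
  long$time_min <- as.numeric(long$time_min)
  dplyr::arrange(long, .data$metabolite, .data$time_min)
}

#' Write a long trait table as wide TSV
#' @param traits long tibble (metabolite, time_min, value).
#' @param path output path.
#' @return `traits`, invisibly.
#' @export
write_trait_table <- function(traits, path) {
  wide <- tidyr::pivot_wider(traits[, c("metabolite", "time_min", "value")],
                             names_from = "time_min", values_from = "value")
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(traits)
}
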