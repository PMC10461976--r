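#' Read and write BED intervals
#'
#' BED files are 0-based half-open; that convention is preserved in the
#' returned tibble (`start` is 0-based, `end` exclusive).
#'
#' @param path File path.
#' @return Tibble with `chrom`, `start`, `end` and, when present, `name`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) {
                   abort(sprintf("malformed BED file %s: %s", path,
                                 conditionMessage(e)))
                 })
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  if (!is.null(gr$name)) out$name <- gr$name
  if (!is.null(gr$score)) out$score <- as.numeric(gr$score)
  st <- as.character(GenomicRanges::strand(gr))
  if (any(st != "*")) out$strand <- if_else(st == "*", ".", st)
  out
}

#' @rdname read_bed
#' @param intervals Tibble with at least `chrom`, `start`, `end`.
#' @export
write_bed <- function(intervals, path) {
  cols <- c("chrom", "start", "end")
  opt <- intersect(c("name", "score", "strand"), names(intervals))
  # BED columns are positional: fill gaps up to the last present column
  if (length(opt) > 0) {
    upto <- max(match(opt, c("name", "score", "strand")))
    need <- c("name", "score", "strand")[seq_len(upto)]
    for (cn in need) {
      if (!cn %in% names(intervals)) {
        intervals[[cn]] <- if (cn == "score") 0 else "."
      }
    }
    cols <- c(cols, need)
  }
  readr::write_tsv(intervals[cols], path, col_names = FALSE)
  invisible(path)
}

#' Read and write FASTA sequences
#'
#' Sequences are upper-cased and line-wrapping removed on read.
#'
#' @param path File path.
#' @return Tibble with `name` and `sequence`.
#' @export
read_fasta <- function(path) {
  ss <- tryCatch(Biostrings::readDNAStringSet(path),
                 error = function(e) {
                   abort(sprintf("malformed FASTA file %s: %s", path,
                                 conditionMessage(e)))
                 })
  tibble(name = names(ss), sequence = unname(toupper(as.character(ss))))
}

#' @rdname read_fasta
#' @param seqs Tibble with `name` (or `element_id`) and `sequence`.
#' @export
write_fasta <- function(seqs, path) {
  nm <- if ("name" %in% names(seqs)) seqs$name else seqs$element_id
  ss <- Biostrings::DNAStringSet(seqs$sequence)
  names(ss) <- nm
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

.read_tsv_checked <- function(path, required, what) {
  df <- tryCatch(readr::read_tsv(path, show_col_types = FALSE,
                                 progress = FALSE),
                 error = function(e) {
                   abort(sprintf("malformed %s file %s: %s", what, path,
                                 conditionMessage(e)))
                 })
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    abort(sprintf("%s file %s is missing column(s): %s", what, path,
                  paste(miss, collapse = ", ")))
  }
  df
}

#' Read a barcode-count table
#'
#' @param path TSV with columns element_id, barcode, sample_id, dna_count,
#'   rna_count.
#' @return Tibble of counts; negative or non-integer counts raise an error
#'   naming the first offending line.
#' @export
read_counts <- function(path) {
  df <- .read_tsv_checked(path, c("element_id", "barcode", "sample_id",
                                  "dna_count", "rna_count"), "counts")
  bad <- which(df$dna_count < 0 | df$rna_count < 0 |
                 df$dna_count != round(df$dna_count) |
                 df$rna_count != round(df$rna_count))
  if (length(bad) > 0) {
    abort(sprintf("counts file %s line %d: counts must be non-negative integers",
                  path, bad[1] + 1L))
  }
  df
}

#' Read a sample sheet (sample_id, line_id, time_point)
#' @param path TSV path.
#' @return Tibble.
#' @export
read_sample_sheet <- function(path) {
  .read_tsv_checked(path, c("sample_id", "time_point"), "sample sheet")
}

#' Read an expression matrix (gene_id plus one RPKM column per sample)
#' @param path TSV path.
#' @return Wide tibble.
#' @export
read_expression <- function(path) {
  df <- .read_tsv_checked(path, "gene_id", "expression")
  vals <- as.matrix(df[setdiff(names(df), "gene_id")])
  if (any(vals < 0, na.rm = TRUE)) {
    abort(sprintf("expression file %s: RPKM values must be non-negative", path))
  }
  if (anyDuplicated(df$gene_id)) {
    abort(sprintf("expression file %s: duplicated gene ids", path))
  }
  df
}

#' Read an enhancer-gene link table (element_id, gene_id)
#' @param path TSV path.
#' @return Tibble.
#' @export
read_links <- function(path) {
  .read_tsv_checked(path, c("element_id", "gene_id"), "links")
}

#' Read JASPAR-format position frequency matrices
#'
#' Accepts the JASPAR text layout: a `>ID name` header followed by four
#' base rows (`A [ 3 10 ... ]` or bare numbers). Counts are normalised to
#' probabilities per position.
#'
#' @param path File path.
#' @param pseudocount Stored on each returned PWM.
#' @return Named list of [pwm()] objects.
#' @export
read_jaspar <- function(path, pseudocount = 0.01) {
  lines <- readLines(path)
  heads <- grep("^>", lines)
  if (length(heads) == 0) abort(sprintf("JASPAR file %s: no '>' headers", path))
  bounds <- c(heads, length(lines) + 1L)
  out <- list()
  for (i in seq_along(heads)) {
    id <- stringr::str_split_1(sub("^>\\s*", "", lines[heads[i]]), "\\s+")[1]
    block <- lines[(heads[i] + 1):(bounds[i + 1] - 1)]
    block <- block[nzchar(trimws(block))]
    if (length(block) < 4) {
      abort(sprintf("JASPAR file %s, motif %s (line %d): expected 4 base rows",
                    path, id, heads[i]))
    }
    rows <- lapply(block[1:4], function(l) {
      nums <- regmatches(l, gregexpr("[0-9.eE+-]+", l))[[1]]
      as.numeric(nums)
    })
    if (length(unique(lengths(rows))) != 1) {
      abort(sprintf("JASPAR file %s, motif %s: ragged matrix rows", path, id))
    }
    counts <- do.call(rbind, rows)  # 4 x positions, rows A C G T
    base_order <- toupper(substr(trimws(block[1:4]), 1, 1))
    if (all(sort(base_order) == sort(.dna_alphabet))) {
      counts <- counts[match(.dna_alphabet, base_order), , drop = FALSE]
    }
    prob <- t(counts) / colSums(counts)
    out[[id]] <- pwm(prob, motif_id = id, pseudocount = pseudocount)
  }
  out
}

#' Read MEME-format motifs
#'
#' Parses the minimal MEME text format: `MOTIF` headers, optional
#' `Background letter frequencies` line, and `letter-probability matrix`
#' blocks.
#'
#' @inheritParams read_jaspar
#' @return Named list of [pwm()] objects.
#' @export
read_meme <- function(path, pseudocount = 0.01) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bg_i <- grep("^Background letter frequencies", lines)
  if (length(bg_i) > 0 && bg_i[1] < length(lines)) {
    toks <- regmatches(lines[bg_i[1] + 1],
                       gregexpr("[0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?",
                                lines[bg_i[1] + 1]))[[1]]
    nums <- as.numeric(toks)
    if (length(nums) == 4) bg <- nums
  }
  starts <- grep("^MOTIF", lines)
  if (length(starts) == 0) abort(sprintf("MEME file %s: no MOTIF blocks", path))
  out <- list()
  for (s in starts) {
    id <- stringr::str_split_1(trimws(sub("^MOTIF", "", lines[s])), "\\s+")[1]
    lp <- grep("letter-probability matrix", lines)
    lp <- lp[lp > s][1]
    if (is.na(lp)) {
      abort(sprintf("MEME file %s, motif %s (line %d): no letter-probability matrix",
                    path, id, s))
    }
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[lp]))
    rows <- lapply(lines[(lp + 1):(lp + w)], function(l) {
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    mat <- do.call(rbind, rows)
    # renormalise: MEME rows are rounded probabilities
    mat <- mat / rowSums(mat)
    out[[id]] <- pwm(mat, motif_id = id, background = bg,
                     pseudocount = pseudocount)
  }
  out
}

#' Write / read a fitted mixture model as JSON
#'
#' @param model An `mpra_mixture`.
#' @param path JSON path.
#' @return `read_model_json()` returns the `mpra_mixture`.
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$ks_pvalue <- m$ks_pvalue %||% NA_real_
  m$ad_pvalue <- m$ad_pvalue %||% NA_real_
  structure(m, class = "mpra_mixture")
}
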