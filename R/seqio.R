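#' Read sequences from a FASTA file
#'
#' A strict FASTA reader. Sequences are uppercased and whitespace-stripped;
#' nucleotide records are restricted to `A`, `C`, `G`, `T`, `N` and protein
#' records to the 20 standard residues plus `X` and `*`. Ambiguity codes
#' other than `N` are rejected rather than silently translated, because the
#' downstream integrity checks depend on unambiguous stop codons.
#'
#' @param path Path to a FASTA file.
#' @param type `"auto"` (default), `"dna"` or `"protein"`. With `"auto"` the
#'   alphabet is inferred from the residues present across the whole file.
#' @return A tibble with columns `id`, `seq` and `length`, one row per
#'   record in file order, with an attribute `type`.
#' @export
read_fasta <- function(path, type = c("auto", "dna", "protein")) {
  type <- match.arg(type)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || !any(nzchar(lines))) {
    abort(paste0("FASTA parse error at line 1: empty file: ", path))
  }
  first <- which(nzchar(lines))[1]
  if (!startsWith(lines[first], ">")) {
    abort(paste0("FASTA parse error at line ", first, ": expected '>' header"))
  }
  ids <- character(); seqs <- character(); hdr_lines <- integer()
  cur <- NULL; cur_line <- NA_integer_; buf <- character()
  flush <- function() {
    if (is.null(cur)) return()
    s <- toupper(gsub("[ \t\r]", "", paste0(buf, collapse = "")))
    if (!nzchar(s)) {
      abort(paste0("FASTA parse error at line ", cur_line,
                   ": record '", cur, "' has an empty sequence"))
    }
    ids <<- c(ids, cur); seqs <<- c(seqs, s); hdr_lines <<- c(hdr_lines, cur_line)
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, ">")) {
      flush()
      cur <- sub("^>\\s*", "", ln)
      cur <- sub("\\s.*$", "", cur)
      if (!nzchar(cur)) abort(paste0("FASTA parse error at line ", i, ": empty header"))
      cur_line <- i
      buf <- character()
    } else if (nzchar(gsub("[ \t\r]", "", ln))) {
      if (is.null(cur)) abort(paste0("FASTA parse error at line ", i, ": sequence before header"))
      buf <- c(buf, ln)
    }
  }
  flush()
  if (anyDuplicated(ids)) {
    abort(paste0("FASTA parse error: duplicated id '", ids[anyDuplicated(ids)], "'"))
  }
  if (type == "auto") {
    pool <- unique(strsplit(paste0(seqs, collapse = ""), "")[[1]])
    type <- if (all(pool %in% c("A", "C", "G", "T", "N"))) "dna" else "protein"
  }
  for (k in seq_along(seqs)) {
    bad <- validate_alphabet(seqs[k], type)
    if (!is.na(bad)) {
      abort(paste0("FASTA parse error at line ", hdr_lines[k], ": record '",
                   ids[k], "' contains illegal character '", bad,
                   "' for type ", type))
    }
  }
  out <- tibble(id = ids, seq = seqs, length = nchar(seqs))
  attr(out, "type") <- type
  out
}

dna_alphabet <- c("A", "C", "G", "T", "N")
protein_alphabet <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                      "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X", "*")

validate_alphabet <- function(seq, type) {
  alpha <- if (type == "dna") dna_alphabet else protein_alphabet
  chars <- strsplit(seq, "")[[1]]
  bad <- chars[!chars %in% alpha]
  if (length(bad)) bad[1] else NA_character_
}

#' Write sequences to a FASTA file
#'
#' Inverse of [read_fasta()]: at a fixed `width`, `write_fasta()` followed by
#' `read_fasta()` reproduces the input records exactly.
#'
#' @param seqs A tibble with columns `id` and `seq`, or a named character
#'   vector.
#' @param path Output path.
#' @param width Line width for the sequence body.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  if (is.character(seqs)) seqs <- tibble(id = names(seqs), seq = unname(seqs))
  stopifnot(all(c("id", "seq") %in% names(seqs)))
  con <- file(path, "wb")
  on.exit(close(con))
  for (k in seq_len(nrow(seqs))) {
    s <- seqs$seq[k]
    starts <- seq(1, nchar(s), by = width)
    body <- substring(s, starts, pmin(starts + width - 1, nchar(s)))
    writeLines(c(paste0(">", seqs$id[k]), body), con, sep = "\n")
  }
  invisible(path)
}

#' Reverse complement of a nucleotide sequence
#'
#' @param seq Character vector of sequences over `A`, `C`, `G`, `T`, `N`
#'   (lowercase accepted).
#' @return Character vector of reverse complements (`N` maps to `N`).
#' @export
revcomp <- function(seq) {
  seq <- toupper(seq)
  bad <- gsub("[ACGTN]", "", seq)
  if (any(nzchar(bad))) {
    abort(paste0("illegal nucleotide character '", substr(bad[nzchar(bad)][1], 1, 1), "'"))
  }
  vapply(seq, function(s) {
    if (!nzchar(s)) return(s)
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Translate a nucleotide sequence in a given frame
#'
#' Codon-by-codon translation with the standard genetic code (these are
#' nuclear nematode loci). Stops are rendered as `*`, codons containing `N`
#' as `X`, and a trailing partial codon is dropped.
#'
#' @param seq A single nucleotide sequence.
#' @param frame 0, 1 or 2: number of leading nucleotides skipped.
#' @return The amino-acid string.
#' @export
translate_seq <- function(seq, frame = 0) {
  stopifnot(length(seq) == 1, frame %in% 0:2)
  seq <- toupper(seq)
  n <- nchar(seq) - frame
  if (n < 3) return("")
  n <- n - n %% 3
  sub <- substr(seq, frame + 1, frame + n)
  as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                     if.fuzzy.codon = "X"))
}

#' Six-frame translation
#'
#' @param seq A single nucleotide sequence.
#' @return A tibble with columns `frame` (+1,+2,+3,-1,-2,-3), `offset`
#'   (leading nucleotides skipped on the translated strand) and `aa`.
#' @export
six_frame <- function(seq) {
  rc <- revcomp(seq)
  tibble(
    frame = c(1L, 2L, 3L, -1L, -2L, -3L),
    offset = rep(0:2, 2),
    aa = c(vapply(0:2, function(f) translate_seq(seq, f), character(1)),
           vapply(0:2, function(f) translate_seq(rc, f), character(1)))
  )
}

# Map a residue span of frame `frame` (1-based in the frame translation)
# back to 1-based nucleotide coordinates on the forward strand of a contig
# of length `len`.
frame_to_nt <- function(frame, aa_start, aa_end, len) {
  off <- abs(frame) - 1
  s <- off + 3 * (aa_start - 1) + 1
  e <- off + 3 * aa_end
  if (frame > 0) c(s, e) else c(len - e + 1, len - s + 1)
}

gff3_types <- c("LTR", "element", "ORF", "motif", "TM", "sequon",
                "GN_region", "GC_region")

#' Write annotation features as GFF3
#'
#' Coordinates are 1-based inclusive throughout the package (GenBank/GFF3
#' convention), so features interleave directly with public annotations.
#'
#' @param features Tibble with columns `seqid`, `start`, `end`, `strand`
#'   (`+`/`-`), `type` (one of `r paste(gff3_types, collapse = ", ")`), and
#'   optionally `attributes` (named list column) and `score`.
#' @param path Output path.
#' @param contig_lengths Optional named vector; coordinates are checked
#'   against it.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path, contig_lengths = NULL) {
  stopifnot(all(c("seqid", "start", "end", "strand", "type") %in% names(features)))
  if (nrow(features)) {
    if (any(!features$type %in% gff3_types)) {
      abort(paste0("unknown feature type: ",
                   paste(setdiff(features$type, gff3_types), collapse = ", ")))
    }
    if (any(features$start < 1) || any(features$start > features$end)) {
      abort("feature coordinates must satisfy 1 <= start <= end")
    }
    if (!is.null(contig_lengths)) {
      lim <- contig_lengths[features$seqid]
      if (any(is.na(lim)) || any(features$end > lim)) {
        abort("feature coordinates out of contig bounds")
      }
    }
  }
  gr <- GenomicRanges::GRanges(
    seqnames = if (nrow(features)) features$seqid else character(),
    ranges = IRanges::IRanges(start = features$start, end = features$end),
    strand = if (nrow(features)) features$strand else character()
  )
  gr$type <- features$type
  gr$source <- rep("evescreen", nrow(features))
  if (!is.null(features$attributes)) {
    keys <- unique(unlist(lapply(features$attributes, names)))
    for (k in keys) {
      GenomicRanges::mcols(gr)[[k]] <-
        vapply(features$attributes, function(a) {
          v <- a[[k]]
          if (is.null(v)) NA_character_ else as.character(v)
        }, character(1))
    }
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 file into a tibble
#'
#' @param path Path to a GFF3 file.
#' @return Tibble with `seqid`, `start`, `end`, `strand`, `type` and one
#'   column per attribute key.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  out <- tibble(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type)
  )
  mc <- as.data.frame(GenomicRanges::mcols(gr))
  for (k in setdiff(names(mc), c("type", "source", "score", "phase"))) {
    v <- mc[[k]]
    out[[k]] <- if (is.list(v)) vapply(v, function(x) {
      if (length(x)) as.character(x[[1]]) else NA_character_
    }, character(1)) else as.character(v)
  }
  out
}

#' Write the per-candidate screening report
#'
#' One row per candidate locus with the element-level summary columns
#' (locus id, element and LTR lengths, LTR identity, polyprotein length,
#' RT motif, Env class, verdict).
#'
#' @param candidates Candidate tibble from [run_screen()] (or
#'   `tidy()` of a screen object).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_report_table <- function(candidates, path) {
  cols <- c("locus_id", "element_length_bp", "ltr_length_bp",
            "ltr_identity_pct", "polyprotein_length_aa", "rt_motif",
            "env_class", "verdict")
  out <- tibble(
    locus_id = character(), element_length_bp = integer(),
    ltr_length_bp = integer(), ltr_identity_pct = double(),
    polyprotein_length_aa = integer(), rt_motif = character(),
    env_class = character(), verdict = character()
  )
  if (!is.null(candidates) && nrow(candidates)) {
    out <- candidates |> dplyr::select(dplyr::all_of(cols))
  }
  readr::write_tsv(out, path)
  invisible(path)
}
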