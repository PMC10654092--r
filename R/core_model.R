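#' Construct a genome assembly
#'
#' The unit of analysis: an ordered set of contigs belonging to one bacterial
#' strain, together with the taxon/strain identifiers used in prophage
#' designations.
#'
#' @param contigs A named `Biostrings::DNAStringSet`, or a named character
#'   vector of DNA sequences (A/C/G/T/N; lowercase accepted and uppercased).
#' @param taxon_id,strain_id Identifiers composing prophage designations.
#' @param species_label Optional free-text species label.
#' @return An object of class `genome_assembly`.
#' @examples
#' asm <- genome_assembly(c(c1 = "ACGTACGT"), taxon_id = "9", strain_id = "X")
#' contig_lengths(asm)
#' @export
genome_assembly <- function(contigs, taxon_id, strain_id, species_label = NA_character_) {
  if (methods::is(contigs, "DNAStringSet")) {
    contigs <- setNames(as.character(contigs), names(contigs))
  }
  if (!is.character(contigs)) {
    abort("`contigs` must be a DNAStringSet or named character vector.",
          class = "prophagr_validation_error")
  }
  contigs <- toupper(contigs)
  if (length(contigs) < 1) {
    abort("An assembly needs at least one contig.", class = "prophagr_parse_error")
  }
  if (is.null(names(contigs)) || anyNA(names(contigs)) || any(names(contigs) == "")) {
    abort("Every contig must be named.", class = "prophagr_validation_error")
  }
  if (anyDuplicated(names(contigs))) {
    abort("Contig ids must be unique within an assembly.",
          class = "prophagr_validation_error")
  }
  bad <- grepl("[^ACGTN]", contigs)
  if (any(bad)) {
    abort(sprintf("Contig %s contains characters outside {A,C,G,T,N}.",
                  names(contigs)[which(bad)[1]]),
          class = "prophagr_validation_error")
  }
  contigs <- Biostrings::DNAStringSet(contigs)
  structure(
    list(taxon_id = as.character(taxon_id),
         strain_id = as.character(strain_id),
         species_label = species_label,
         contigs = contigs),
    class = "genome_assembly"
  )
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat(sprintf("<genome_assembly> taxon %s strain %s: %d contig(s), %s bp\n",
              x$taxon_id, x$strain_id, length(x$contigs),
              format(sum(Biostrings::width(x$contigs)), big.mark = ",")))
  invisible(x)
}

#' Contig lengths of an assembly
#' @param assembly A `genome_assembly`.
#' @return Named integer vector of contig lengths (bp).
#' @export
contig_lengths <- function(assembly) {
  setNames(Biostrings::width(assembly$contigs), names(assembly$contigs))
}

#' Number of contigs in an assembly
#' @param assembly A `genome_assembly`.
#' @return Integer contig count.
#' @export
contig_count <- function(assembly) length(assembly$contigs)

#' Read a genome assembly from FASTA
#'
#' Contigs are kept in file order and uppercased. Draft assemblies with more
#' than `config$max_contigs` contigs are rejected with an admission error --
#' the published corpus was restricted to assemblies of 100 contigs or fewer
#' because prophage discovery degrades in fragmented assemblies -- unless
#' `enforce_admission = FALSE`.
#'
#' @param fasta_source Path to a (multi-record) FASTA file.
#' @param taxon_id,strain_id Identifiers for designations.
#' @param species_label Optional species label.
#' @param config A [pipeline_config()].
#' @param enforce_admission Apply the contig-count admission rule?
#' @return A `genome_assembly`.
#' @export
read_assembly <- function(fasta_source, taxon_id, strain_id,
                          species_label = NA_character_,
                          config = pipeline_config(),
                          enforce_admission = TRUE) {
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(fasta_source),
    error = function(e) abort(sprintf("Could not parse FASTA '%s': %s",
                                      fasta_source, conditionMessage(e)),
                              class = "prophagr_parse_error")
  )
  if (length(seqs) == 0) {
    abort(sprintf("FASTA '%s' contains no records.", fasta_source),
          class = "prophagr_parse_error")
  }
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (enforce_admission && length(seqs) > config$max_contigs) {
    abort(sprintf("Assembly has %d contigs; admission rule allows at most %d.",
                  length(seqs), config$max_contigs),
          class = "prophagr_admission_error")
  }
  genome_assembly(seqs, taxon_id, strain_id, species_label)
}

#' Write an assembly (or any named sequence set) to FASTA
#'
#' @param x A `genome_assembly`, `DNAStringSet`, or named character vector.
#' @param path Output path. Sequences are wrapped at 60 columns.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (inherits(x, "genome_assembly")) x <- x$contigs
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path, width = 60)
  invisible(path)
}

#' Prophage designation
#'
#' Formats the `prophi<taxon>.<strain>-<index>` designation carried by every
#' prophage call; e.g. taxon 1761, strain 28 yields `prophi1761.28-1`,
#' `prophi1761.28-2`, ...
#'
#' @param taxon_id,strain_id Identifiers of the host strain.
#' @param index 1-based prophage index within the strain (ordered by genomic
#'   position of the left boundary).
#' @return Character designation.
#' @examples
#' make_designation("1761", "28", 1)
#' @export
make_designation <- function(taxon_id, strain_id, index) {
  index <- as.integer(index)
  if (any(is.na(index)) || any(index < 1)) {
    abort("`index` must be >= 1.", class = "prophagr_validation_error")
  }
  sprintf("prophi%s.%s-%d", taxon_id, strain_id, index)
}

#' Reverse complement of a DNA string
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Extract a subsequence from an assembly
#'
#' Intervals are 1-based inclusive. Strand `-` returns the reverse complement
#' of the forward-strand slice.
#'
#' @param assembly A `genome_assembly`.
#' @param contig_id Contig to slice.
#' @param start,end 1-based inclusive interval; `end >= start`.
#' @param strand `"+"` or `"-"`.
#' @return Character DNA string of length `end - start + 1`.
#' @export
extract_subsequence <- function(assembly, contig_id, start, end, strand = "+") {
  if (!contig_id %in% names(assembly$contigs)) {
    abort(sprintf("Unknown contig '%s'.", contig_id), class = "prophagr_lookup_error")
  }
  len <- length(assembly$contigs[[contig_id]])
  if (start < 1 || end > len || end < start) {
    abort(sprintf("Interval [%d, %d] out of bounds for contig '%s' (length %d).",
                  start, end, contig_id, len),
          class = "prophagr_range_error")
  }
  s <- as.character(Biostrings::subseq(assembly$contigs[[contig_id]], start, end))
  if (identical(strand, "-")) revcomp(s) else s
}

# ---- gene features -----------------------------------------------------------

#' Assemble a gene feature table
#'
#' Normalizes gene annotations into the tibble every downstream operation
#' consumes: one row per gene with 1-based inclusive coordinates and a `rank`
#' column giving the ordinal position of the gene along its contig (1-based,
#' increasing with `start`).
#'
#' @param genes A data frame with columns `gene_id`, `contig_id`, `start`,
#'   `end`, `strand`, `protein`.
#' @return A tibble with the same columns plus `rank`, sorted by
#'   (`contig_id`, `start`).
#' @export
as_gene_table <- function(genes) {
  need <- c("gene_id", "contig_id", "start", "end", "strand", "protein")
  missing <- setdiff(need, names(genes))
  if (length(missing)) {
    abort(sprintf("Gene table lacks column(s): %s.", paste(missing, collapse = ", ")),
          class = "prophagr_validation_error")
  }
  if (anyDuplicated(genes$gene_id)) {
    abort("Duplicate gene_id in gene table.", class = "prophagr_validation_error")
  }
  if (any(!nzchar(genes$protein))) {
    abort("Every gene needs a non-empty protein sequence.",
          class = "prophagr_validation_error")
  }
  genes %>%
    as_tibble() %>%
    mutate(start = as.integer(.data$start), end = as.integer(.data$end)) %>%
    arrange(.data$contig_id, .data$start) %>%
    group_by(.data$contig_id) %>%
    mutate(rank = row_number()) %>%
    ungroup() %>%
    select(dplyr::all_of(need), "rank")
}

#' Read gene features from a 6-column TSV
#'
#' Columns: gene_id, contig_id, start, end, strand, protein (1-based inclusive
#' coordinates, header optional and autodetected).
#'
#' @param path TSV path.
#' @return A gene table (see [as_gene_table()]).
#' @export
read_gene_tsv <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("gene_id", first, fixed = TRUE)
  df <- if (has_header) {
    utils::read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, quote = "")
  } else {
    utils::read.table(path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE, quote = "",
                      col.names = c("gene_id", "contig_id", "start", "end",
                                    "strand", "protein"))
  }
  as_gene_table(df)
}

#' Read CDS features from a GFF3 file
#'
#' Uses `rtracklayer` for parsing; protein sequences must be supplied through
#' the `translation` attribute or joined afterwards.
#'
#' @param path GFF3 path.
#' @return A gene table (see [as_gene_table()]).
#' @export
read_gene_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("Reading GFF3 requires the rtracklayer package.",
          class = "prophagr_validation_error")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "CDS"]
  prot <- if ("translation" %in% names(S4Vectors::mcols(gr))) gr$translation else NA_character_
  as_gene_table(tibble(
    gene_id = gr$ID,
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    protein = prot
  ))
}

#' Write genomic regions as GFF3
#'
#' One feature per region with its class list in the attributes column
#' (1-based inclusive coordinates, GFF3 convention).
#'
#' @param regions A region tibble from [scan_regions()] / [classify_regions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_gff3 <- function(regions, path) {
  lines <- c("##gff-version 3")
  if (nrow(regions)) {
    classes <- if ("classes" %in% names(regions)) {
      vapply(regions$classes, function(x) paste(x, collapse = ","), character(1))
    } else rep("", nrow(regions))
    lines <- c(lines, sprintf(
      "%s\tprophagr\tregion\t%d\t%d\t.\t.\t.\tID=region_%d;classes=%s",
      regions$contig_id, regions$start, regions$end,
      seq_len(nrow(regions)), classes))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a tibble as TSV
#' @param x A data frame. List columns are collapsed with commas.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(x, path) {
  x <- as.data.frame(lapply(x, function(col) {
    if (is.list(col)) vapply(col, function(e) paste(unlist(e), collapse = ","), character(1))
    else col
  }), stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
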