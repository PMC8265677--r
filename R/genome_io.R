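#' Genome container
#'
#' A minimal in-memory genome: an ordered set of uppercase chromosome
#' sequences plus their lengths. All coordinates in this package are
#' 0-based half-open; conversion to and from 1-based conventions happens
#' only at file boundaries (GFF3, qPCR site names).
#'
#' @param seqs named character vector of uppercase DNA sequences
#' @return an object of class `Genome` with elements `seqs` and `lengths`
#' @export
new_genome <- function(seqs) {
  stopifnot(is.character(seqs), length(seqs) >= 1)
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("all chromosomes must be named")
  if (anyDuplicated(names(seqs)))
    stop("duplicate chromosome name: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  seqs <- toupper(seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("sequence contains non-ACGTN characters: ",
         paste(names(seqs)[bad], collapse = ", "))
  structure(list(seqs = seqs, lengths = stats::setNames(nchar(seqs), names(seqs))),
            class = "Genome")
}

#' @export
print.Genome <- function(x, ...) {
  cat("Genome:", length(x$seqs), "chromosome(s),",
      format(sum(x$lengths), big.mark = ","), "bp total\n")
  invisible(x)
}

#' Read a multi-record FASTA file into a Genome
#'
#' Lowercase input is upcased; `N` is allowed. Record names are taken up to
#' the first whitespace. Duplicate names and empty files are errors.
#'
#' @param path path to a FASTA file
#' @return a [new_genome()] object
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- tryCatch(Biostrings::readDNAStringSet(path),
                 error = function(e) stop("FASTA parse error in '", path,
                                          "': ", conditionMessage(e)))
  if (length(ss) == 0) stop("no records in FASTA file: ", path)
  nm <- sub("\\s.*$", "", names(ss))
  seqs <- stats::setNames(as.character(ss), nm)
  new_genome(seqs)
}

#' Write a Genome to FASTA
#' @param genome a `Genome`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome$seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Keeps features of type `gene`, converts the file's 1-based inclusive
#' coordinates to 0-based half-open, and derives the TSS (start for `+`
#' genes, end-1 for `-` genes). Genes on unknown chromosomes, beyond
#' chromosome ends, or with strand `.` are errors.
#'
#' @param path path to a GFF3 file
#' @param genome a `Genome` the annotation must match
#' @return data.frame with columns gene_id, chrom, start, end, strand, tss
#'   (start/end 0-based half-open)
#' @export
read_gff3_genes <- function(path, genome) {
  gff <- rtracklayer::readGFF(path)
  gff <- as.data.frame(gff)
  gff <- gff[gff$type == "gene", , drop = FALSE]
  if (nrow(gff) == 0) stop("no gene features in ", path)
  chrom <- as.character(gff$seqid)
  unknown <- setdiff(unique(chrom), names(genome$seqs))
  if (length(unknown))
    stop("unknown chromosome(s) in annotation: ", paste(unknown, collapse = ", "))
  strand <- as.character(gff$strand)
  if (any(!strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'; found: ",
         paste(unique(strand[!strand %in% c("+", "-")]), collapse = ", "))
  id <- gff$ID
  if (is.null(id) || any(is.na(id) | id == ""))
    stop("every gene feature needs an ID attribute")
  start0 <- as.integer(gff$start) - 1L
  end0 <- as.integer(gff$end)
  len <- unname(genome$lengths[chrom])
  bad <- start0 < 0L | start0 >= end0 | end0 > len
  if (any(bad))
    stop("gene interval outside chromosome: ",
         paste(id[bad], collapse = ", "))
  genes <- data.frame(
    gene_id = as.character(id),
    chrom = chrom,
    start = start0,
    end = end0,
    strand = strand,
    tss = ifelse(strand == "+", start0, end0 - 1L),
    stringsAsFactors = FALSE
  )
  rownames(genes) <- NULL
  genes
}

#' Write gene models back to GFF3
#'
#' Inverse of [read_gff3_genes()]: internal 0-based half-open intervals are
#' emitted as 1-based inclusive GFF3 `gene` features.
#'
#' @param genes data.frame as returned by [read_gff3_genes()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_gff3_genes <- function(genes, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tsixmaDyn\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$chrom, genes$start + 1L, genes$end,
                     genes$strand, genes$gene_id))
  writeLines(lines, path)
  invisible(path)
}

#' Index all ApT duplexes of a genome
#'
#' An ApT duplex is a 5'-ApT-3' dinucleotide on the Watson strand: base
#' pairing puts an A on the Crick strand at `watson_pos + 1` whose own 3'
#' neighbour is T, so both strands read ApT and the two adenines form the
#' unit of symmetric/hemimethylated analysis. N never forms a duplex.
#'
#' @param genome a `Genome`
#' @return data.frame with columns chrom, watson_pos, crick_pos (0-based;
#'   crick_pos = watson_pos + 1)
#' @export
index_apt_duplexes <- function(genome) {
  res <- lapply(names(genome$seqs), function(ch) {
    m <- gregexpr("(?=AT)", genome$seqs[[ch]], perl = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    data.frame(chrom = ch, watson_pos = as.integer(m) - 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(chrom = character(), watson_pos = integer())
  out$crick_pos <- out$watson_pos + 1L
  rownames(out) <- NULL
  out
}

#' Reference base at a set of positions (Watson strand reading)
#' @keywords internal
base_at <- function(genome, chrom, pos) {
  s <- genome$seqs[chrom]
  out <- substr(s, pos + 1L, pos + 1L)
  out[pos < 0L | pos >= genome$lengths[chrom]] <- ""
  unname(out)
}

#' Is an adenine in ApT context?
#'
#' Strand-local test: a Watson-strand A at `pos` is ApT iff the Watson base
#' at `pos + 1` is T; a Crick-strand A at `pos` (i.e. Watson base T at
#' `pos`) is ApT iff the Watson base at `pos - 1` is A (the Crick 3'
#' neighbour). Positions whose 3' neighbour falls off the chromosome are
#' never ApT. Vectorised over `chrom`, `pos`, `strand`.
#'
#' @param genome a `Genome`
#' @param chrom chromosome name(s)
#' @param pos 0-based coordinate(s) of the adenine (Watson coordinate even
#'   for Crick-strand adenines)
#' @param strand "+" or "-"
#' @return logical vector
#' @export
is_apt_context <- function(genome, chrom, pos, strand) {
  n <- max(length(chrom), length(pos), length(strand))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  strand <- rep_len(strand, n)
  nb <- ifelse(strand == "+", pos + 1L, pos - 1L)
  want <- ifelse(strand == "+", "T", "A")
  base_at(genome, chrom, nb) == want
}
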