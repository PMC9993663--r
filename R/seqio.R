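#' @title Sequence and table input/output
#' @description Readers and writers for the external formats the classifier
#'   touches: FASTA and FASTQ sequences, the genome lineage map, Kraken-style
#'   first-pass per-read output, and the package's own assignment table.
#' @name seqio
NULL

new_seq_records <- function(id = character(), desc = character(),
                            seq = character()) {
    stopifnot(length(id) == length(seq))
    data.frame(id = as.character(id), desc = as.character(desc),
               seq = toupper(as.character(seq)), stringsAsFactors = FALSE)
}

split_header <- function(headers) {
    headers <- sub("^[>@]", "", headers)
    id <- sub("\\s.*$", "", headers)
    desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
    list(id = id, desc = desc)
}

#' Read a FASTA file
#'
#' Records are returned in file order; wrapped sequence lines are
#' concatenated and residues are uppercased. The record id is the first
#' whitespace-delimited token of the header, the remainder is kept as the
#' description.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns \code{id}, \code{desc}, \code{seq}.
#' @export
read_fasta <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    nonblank <- lines[nzchar(trimws(lines))]
    if (length(nonblank) == 0) return(new_seq_records())
    if (!startsWith(nonblank[1], ">"))
        stop("sequence data before first FASTA header in ", path)
    set <- Biostrings::readDNAStringSet(path, format = "fasta")
    h <- split_header(names(set))
    if (any(!nzchar(h$id))) stop("empty record id in ", path)
    new_seq_records(h$id, h$desc, as.character(set))
}

#' Write records as FASTA
#'
#' @param records Data frame with columns \code{id}, \code{desc}, \code{seq}.
#' @param path Output path.
#' @param width Line-wrap width for sequence lines.
#' @return Invisibly, \code{path}.
#' @export
write_fasta <- function(records, path, width = 60L) {
    set <- Biostrings::DNAStringSet(setNames(
        records$seq,
        ifelse(nzchar(records$desc), paste(records$id, records$desc),
               records$id)))
    Biostrings::writeXStringSet(set, path, width = width)
    invisible(path)
}

#' Read metagenomic reads from FASTA or FASTQ
#'
#' FASTQ quality strings are discarded; records arrive in file order. With
#' \code{format = "auto"} the dialect is sniffed from the first byte
#' (\code{>} for FASTA, \code{@} for FASTQ).
#'
#' @param path Path to the read file.
#' @param format One of \code{"auto"}, \code{"fasta"}, \code{"fastq"}.
#' @return A data frame with columns \code{id}, \code{desc}, \code{seq}.
#' @export
read_reads <- function(path, format = c("auto", "fasta", "fastq")) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("file not found: ", path)
    if (format == "auto") {
        first <- substr(readLines(path, n = 1L, warn = FALSE)[1], 1, 1)
        if (identical(first, ">")) format <- "fasta"
        else if (identical(first, "@")) format <- "fastq"
        else stop("cannot determine read format of ", path,
                  ": first byte is neither '>' nor '@'")
    }
    if (format == "fasta") return(read_fasta(path))
    lines <- readLines(path, warn = FALSE)
    while (length(lines) && !nzchar(lines[length(lines)]))
        lines <- lines[-length(lines)]
    if (length(lines) %% 4L != 0L)
        stop("truncated FASTQ record starting at line ",
             4L * (length(lines) %/% 4L) + 1L, " of ", path)
    set <- Biostrings::readDNAStringSet(path, format = "fastq")
    h <- split_header(names(set))
    new_seq_records(h$id, h$desc, as.character(set))
}

#' Write reads as FASTQ with placeholder qualities
#'
#' @inheritParams write_fasta
#' @return Invisibly, \code{path}.
#' @export
write_fastq <- function(records, path) {
    hdr <- ifelse(nzchar(records$desc), paste(records$id, records$desc),
                  records$id)
    qual <- vapply(nchar(records$seq),
                   function(n) paste(rep("I", n), collapse = ""), "")
    writeLines(as.vector(rbind(paste0("@", hdr), records$seq, "+", qual)),
               path)
    invisible(path)
}

#' Read a genome lineage map
#'
#' Two-column TSV: genome id, then the six-rank lineage
#' (phylum;class;order;family;genus;species) joined by semicolons. Unknown
#' ranks carry the sentinel token \code{"NA"}.
#'
#' @param path Path to the TSV file.
#' @return A data frame with column \code{genome_id} plus one column per
#'   rank in \code{\link{lineage_ranks}()} order.
#' @export
read_lineage_map <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    tab <- read.delim(path, header = FALSE, colClasses = "character",
                      quote = "", comment.char = "")
    if (ncol(tab) != 2L)
        stop("lineage map must have exactly 2 tab-separated columns, got ",
             ncol(tab))
    if (anyDuplicated(tab[[1]]))
        stop("duplicate genome_id in lineage map: ",
             tab[[1]][duplicated(tab[[1]])][1])
    parts <- strsplit(tab[[2]], ";", fixed = TRUE)
    bad <- lengths(parts) != 6L
    if (any(bad))
        stop("lineage for genome '", tab[[1]][bad][1], "' has ",
             lengths(parts)[bad][1], " ranks, expected 6")
    lin <- do.call(rbind, parts)
    colnames(lin) <- lineage_ranks()
    out <- data.frame(genome_id = tab[[1]], lin, stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

#' Write a genome lineage map
#'
#' @param lineage_map Data frame as returned by \code{\link{read_lineage_map}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_lineage_map <- function(lineage_map, path) {
    lin <- apply(lineage_map[, lineage_ranks(), drop = FALSE], 1L,
                 paste, collapse = ";")
    writeLines(paste(lineage_map$genome_id, lin, sep = "\t"), path)
    invisible(path)
}

#' Parse Kraken-style per-read classifier output
#'
#' Consumes the first four tab-separated columns: status (\code{C} or
#' \code{U}), read id, taxon, read length. Any further columns (such as the
#' k-mer LCA mapping string) are ignored.
#'
#' @param path Path to the classifier output TSV.
#' @return A data frame with columns \code{status}, \code{read_id},
#'   \code{taxon}, \code{read_length}.
#' @export
parse_kraken_output <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0)
        return(data.frame(status = character(), read_id = character(),
                          taxon = character(), read_length = integer(),
                          stringsAsFactors = FALSE))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    short <- lengths(parts) < 4L
    if (any(short))
        stop("line ", which(short)[1],
             ": expected >= 4 tab-separated columns")
    status <- vapply(parts, `[[`, "", 1L)
    bad <- !status %in% c("C", "U")
    if (any(bad))
        stop("line ", which(bad)[1], ": status must be 'C' or 'U', got '",
             status[bad][1], "'")
    data.frame(status = status,
               read_id = vapply(parts, `[[`, "", 2L),
               taxon = vapply(parts, `[[`, "", 3L),
               read_length = as.integer(vapply(parts, `[[`, "", 4L)),
               stringsAsFactors = FALSE)
}

#' Write and read the per-read, per-rank assignment table
#'
#' One row per read and rank: \code{read_id}, \code{rank}, \code{taxon},
#' \code{probability} (6 decimal places), \code{assigned} (\code{0}/\code{1}).
#'
#' @param assignments Assignment data frame from
#'   \code{\link{classify_reads}} or \code{\link{hybrid_merge}}.
#' @param path Output path.
#' @return Invisibly, \code{path}; \code{read_assignments} returns the
#'   parsed data frame.
#' @export
write_assignments <- function(assignments, path) {
    out <- assignments[, c("read_id", "rank", "taxon", "probability",
                           "assigned")]
    out$probability <- ifelse(is.na(out$probability), "NA",
                              sprintf("%.6f", out$probability))
    out$assigned <- as.integer(out$assigned)
    out$taxon[is.na(out$taxon)] <- "NA"
    out$rank[is.na(out$rank)] <- "NA"
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname write_assignments
#' @export
read_assignments <- function(path) {
    tab <- read.delim(path, colClasses = "character", quote = "")
    tab$probability <- suppressWarnings(as.numeric(tab$probability))
    tab$assigned <- as.integer(tab$assigned) == 1L
    tab
}
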