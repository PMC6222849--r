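#' Read protein sequences from FASTA with strict residue validation
#'
#' Reads a FASTA file into an [Biostrings::AAStringSet] and validates every
#' record against the 20-letter standard amino-acid alphabet. Lowercase
#' residues are uppercased; any other character — including the ambiguity
#' codes B, U, X, Z and the stop character `*` — aborts with an error naming
#' the offending record and character. Wrapped (multi-line) records are
#' concatenated by the parser.
#'
#' Validation is total: every record either becomes a sequence in the result
#' or raises a named error; characters are never silently dropped.
#'
#' @param path Path to a FASTA file.
#' @param label Optional class label attached to every record
#'   (1 = virion/positive, 0 = non-virion/negative, NA = unlabeled).
#' @return An `AAStringSet`; `mcols(x)$label` holds the class label.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "ACDE", ">s2", "mkly"), tf)
#' seqs <- readProteinFasta(tf, label = 1)
#' as.character(seqs)
#' @export
readProteinFasta <- function(path, label = NA) {
    if (!file.exists(path))
        stop("cannot read FASTA file: ", path)
    seqs <- Biostrings::readAAStringSet(path)
    if (length(seqs) == 0L)
        stop("FASTA file contains no records: ", path)
    chars <- toupper(as.character(seqs))
    ids <- sub("\\s.*$", "", names(seqs))
    validateResidues(chars, ids)
    out <- Biostrings::AAStringSet(chars)
    names(out) <- ids
    S4Vectors::mcols(out)$label <- rep(as.numeric(label), length(out))
    dups <- ids[duplicated(ids)]
    if (length(dups))
        message("duplicate ids on read (kept): ", paste(unique(dups), collapse = ", "))
    out
}

## Hard check: every character in the 20-letter alphabet, no empty records.
validateResidues <- function(chars, ids) {
    for (i in seq_along(chars)) {
        if (!nzchar(chars[i]))
            stop("record '", ids[i], "' has an empty sequence")
        bad <- setdiff(unique(strsplit(chars[i], "")[[1]]), AA_ALPHABET20)
        if (length(bad))
            stop("record '", ids[i], "' contains non-standard residue(s): ",
                 paste(bad, collapse = ", "))
    }
    invisible(TRUE)
}

#' Write protein sequences to FASTA
#'
#' Round-trip safe with [readProteinFasta()]: ids and residues are
#' reproduced exactly. An empty set writes an empty file.
#'
#' @param seqs An `AAStringSet` (or named character vector of residues).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeProteinFasta <- function(seqs, path) {
    if (is.character(seqs))
        seqs <- Biostrings::AAStringSet(seqs)
    if (length(seqs) == 0L) {
        file.create(path)
        return(invisible(path))
    }
    validateResidues(as.character(seqs), names(seqs))
    Biostrings::writeXStringSet(seqs, path)
    invisible(path)
}
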