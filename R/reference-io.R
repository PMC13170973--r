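#' Read a multi-sequence reference FASTA
#'
#' Each reference sequence is a "taxon" for reporting purposes, whether it
#' is a chromosome, strain, plasmid or other genomic entity. Taxon ids are
#' the first whitespace-delimited header token and must be unique.
#'
#' @param path FASTA file (plain or gzip).
#' @return a [Biostrings::DNAStringSet] named by taxon id.
#' @export
readReference <- function(path) {
  ref <- Biostrings::readDNAStringSet(path)
  names(ref) <- firstToken(names(ref))
  if (anyDuplicated(names(ref))) {
    dup <- unique(names(ref)[duplicated(names(ref))])
    stop("reference FASTA has duplicated taxon id(s): ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  if (any(Biostrings::width(ref) == 0L)) {
    stop("reference FASTA contains an empty sequence", call. = FALSE)
  }
  ref
}
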