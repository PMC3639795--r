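# Reading genomes and annotations; elementary sequence operations.
# Internal coordinates are 0-based half-open; conversion to/from the 1-based
# inclusive convention happens only at the GFF3/TSV boundaries.

#' Read genome sequences from a FASTA file
#'
#' Sequences are uppercased and U is mapped to T. Ambiguity codes other than
#' N are rejected: the downstream grammar scan is defined on \{A,C,G,T,N\}.
#'
#' @param path path to a (multi-entry) FASTA file
#' @return a named character vector of genome sequences, in file order
#' @export
readGenomeFasta <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    set <- Biostrings::readBStringSet(path)
    seqs <- chartr("U", "T", toupper(as.character(set)))
    # FASTA ids: first whitespace-delimited token
    names(seqs) <- sub("\\s.*$", "", names(set))
    bad <- grepl("[^ACGTN]", seqs)
    if (any(bad))
        stop("sequence(s) ", paste(names(seqs)[bad], collapse = ", "),
             " contain characters outside {A,C,G,T,N,U}")
    if (any(nchar(seqs) == 0L)) stop("empty sequence in FASTA")
    if (anyDuplicated(names(seqs))) stop("duplicated genome ids in FASTA")
    seqs
}

#' Write genome sequences to FASTA
#'
#' @param seqs named character vector of sequences
#' @param path output path
#' @export
writeGenomeFasta <- function(seqs, path) {
    set <- Biostrings::DNAStringSet(seqs)
    Biostrings::writeXStringSet(set, path)
    invisible(path)
}

.RNA_GENE_TYPES <- c("tRNA", "rRNA", "ncRNA", "tmRNA", "RNase_P_RNA",
                     "SRP_RNA", "antisense_RNA", "misc_RNA")

#' Read gene annotations from a GFF3 file
#'
#' Features are classified as \code{protein_coding} (type CDS),
#' \code{rna_gene} (tRNA/rRNA/ncRNA and friends) or \code{other}. A feature
#' is confident unless its product description contains one of the words
#' pseudo, predicted, putative, unknown, possible, hypothetical or probable
#' (case-insensitively), or it carries a pseudo flag. Features extending
#' beyond their genome sequence are dropped with a warning.
#'
#' @param path path to a GFF3 file
#' @param genomes named character vector of genome sequences (used for
#'   bounds checking); annotations must use the same sequence names
#' @return a \code{GRanges} with metadata columns \code{kind},
#'   \code{product} and \code{isConfident}
#' @export
readAnnotationsGff <- function(path, genomes = NULL) {
    if (!file.exists(path)) stop("no such file: ", path)
    gr <- rtracklayer::import(path, format = "gff3")
    mc <- S4Vectors::mcols(gr)
    type <- as.character(mc$type)
    kind <- rep("other", length(gr))
    kind[type == "CDS"] <- "protein_coding"
    kind[type %in% .RNA_GENE_TYPES] <- "rna_gene"
    product <- if ("product" %in% names(mc)) {
        vapply(mc$product, function(p) {
            if (length(p) == 0 || all(is.na(p))) "" else paste(p, collapse = " ")
        }, character(1))
    } else rep("", length(gr))
    pseudo <- if ("pseudo" %in% names(mc)) {
        !is.na(mc$pseudo) & tolower(as.character(mc$pseudo)) %in%
            c("true", "1", "yes", "")
    } else rep(FALSE, length(gr))
    isConfident <- .isConfidentProduct(product) & !pseudo
    out <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                  IRanges::ranges(gr),
                                  strand = GenomicRanges::strand(gr))
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(kind = kind,
                                                  product = product,
                                                  isConfident = isConfident)
    if (!is.null(genomes)) {
        gid <- as.character(GenomicRanges::seqnames(out))
        known <- gid %in% names(genomes)
        if (!all(known)) {
            warning(sum(!known), " feature(s) on unknown sequences dropped")
            out <- out[known]
            gid <- gid[known]
        }
        lens <- nchar(genomes)[gid]
        ok <- GenomicRanges::start(out) >= 1 & GenomicRanges::end(out) <= lens
        if (!all(ok)) {
            warning(sum(!ok),
                    " feature(s) with coordinates outside their sequence dropped")
            out <- out[ok]
        }
    }
    out
}

#' Write annotations as GFF3
#'
#' @param annotations a \code{GRanges} as produced by
#'   \code{\link{readAnnotationsGff}}
#' @param path output path
#' @export
writeAnnotationsGff <- function(annotations, path) {
    gr <- annotations
    mc <- S4Vectors::mcols(gr)
    type <- rep("gene", length(gr))
    type[mc$kind == "protein_coding"] <- "CDS"
    type[mc$kind == "rna_gene"] <- "ncRNA"
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(type = type,
                                                 product = mc$product)
    rtracklayer::export(gr, path, format = "gff3")
    invisible(path)
}

#' Reverse complement of a nucleotide string
#'
#' Standard reverse complement over \{A,C,G,T,N\}; N maps to N. Vectorized.
#'
#' @param seq character vector of nucleotide strings
#' @return character vector of reverse complements
#' @export
revComp <- function(seq) {
    if (length(seq) == 0) return(character(0))
    bad <- grepl("[^ACGTN]", seq)
    if (any(bad)) stop("revComp is defined on {A,C,G,T,N} only")
    out <- chartr("ACGTN", "TGCAN", seq)
    vapply(out, function(s) {
        if (nchar(s) == 0) return("")
        paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
    }, character(1), USE.NAMES = FALSE)
}

#' Translate a nucleotide sequence (translation table 11)
#'
#' A trailing partial codon is dropped, so the peptide length is always
#' \code{floor(nchar(nt) / 3)}. An in-frame TAG is rendered as the
#' pyrrolysine placeholder \code{O} when \code{amberAsPyl = TRUE} and as
#' \code{*} otherwise; other stop codons give \code{*}; codons containing N
#' give \code{X}.
#'
#' @param nt character vector of nucleotide strings
#' @param amberAsPyl render TAG as \code{O} instead of \code{*}
#' @return character vector of amino-acid strings
#' @export
translateCodons <- function(nt, amberAsPyl = FALSE) {
    gc <- .geneticCode()
    vapply(nt, function(s) {
        cods <- .codons(s)
        if (length(cods) == 0L) return("")
        aa <- unname(gc[cods])
        aa[is.na(aa)] <- "X"
        if (amberAsPyl) aa[cods == "TAG"] <- "O"
        paste(aa, collapse = "")
    }, character(1), USE.NAMES = FALSE)
}
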