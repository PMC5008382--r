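#' @import methods
#' @importClassesFrom Biostrings RNAStringSet
NULL

#' Hairpin reference with mature-arm annotations
#'
#' A `ReferenceSet` bundles miRNA precursor (hairpin) sequences with the
#' coordinates of their annotated mature arms.  It is the template against
#' which isomiRs are defined: a read end matching the hairpin continuation is
#' templated (trimming/elongation), a read end that does not match is a
#' non-templated addition (NTA).
#'
#' Mature coordinates are 0-based half-open (`[start, end)`) on the hairpin's
#' 5'->3' sense strand; the canonical mature sequence is the exact hairpin
#' substring `[start, end)`.
#'
#' @slot hairpins An [Biostrings::RNAStringSet] of precursor sequences,
#'   names are hairpin ids.
#' @slot matures A `data.frame` with columns `mirna_id`, `hairpin_id`,
#'   `start`, `end`, `arm` (one of `"5p"`, `"3p"`).
#'
#' @seealso [ReferenceSet()], [loadReference()], [templatedSuffix()],
#'   [makeToyReference()]
#' @aliases ReferenceSet-class
#' @exportClass ReferenceSet
setClass("ReferenceSet",
         slots = c(hairpins = "RNAStringSet", matures = "data.frame"))

setValidity("ReferenceSet", function(object) {
  hp <- object@hairpins
  ma <- object@matures
  msgs <- character()
  if (is.null(names(hp)) || anyDuplicated(names(hp)))
    msgs <- c(msgs, "hairpins must have unique names")
  if (any(Biostrings::width(hp) == 0L))
    msgs <- c(msgs, "hairpin sequences must be non-empty")
  need <- c("mirna_id", "hairpin_id", "start", "end", "arm")
  if (!all(need %in% colnames(ma)))
    return(paste("matures must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(ma$mirna_id))
    msgs <- c(msgs, "mirna_id must be unique")
  if (!all(ma$arm %in% c("5p", "3p")))
    msgs <- c(msgs, "arm must be '5p' or '3p'")
  missing_hp <- setdiff(ma$hairpin_id, names(hp))
  if (length(missing_hp))
    msgs <- c(msgs, paste0("annotation references missing hairpin(s): ",
                           paste(missing_hp, collapse = ", ")))
  ok <- ma$hairpin_id %in% names(hp)
  if (any(ok)) {
    w <- Biostrings::width(hp)[match(ma$hairpin_id[ok], names(hp))]
    bad <- ma$start[ok] < 0L | ma$start[ok] >= ma$end[ok] | ma$end[ok] > w
    if (any(bad))
      msgs <- c(msgs, paste0("malformed mature coordinates for: ",
                             paste(ma$mirna_id[ok][bad], collapse = ", ")))
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a ReferenceSet
#'
#' @param hairpins Named character vector, `DNAStringSet` or `RNAStringSet`
#'   of hairpin sequences.  `T` is converted to `U`; sequences are stored as
#'   RNA.
#' @param matures `data.frame` with columns `mirna_id`, `hairpin_id`,
#'   `start` (0-based inclusive), `end` (0-based exclusive), `arm`.
#' @return A validated [ReferenceSet-class] object.
#' @examples
#' ref <- ReferenceSet(
#'   c(hp1 = "AAAAUAGCUUAUCAGACUGAUGUUGAGGGG"),
#'   data.frame(mirna_id = "miR-x", hairpin_id = "hp1",
#'              start = 4, end = 26, arm = "5p"))
#' canonicalSequence(ref, "miR-x")
#' @export
ReferenceSet <- function(hairpins, matures) {
  if (is(hairpins, "XStringSet")) hairpins <- as.character(hairpins)
  nms <- names(hairpins)
  seqs <- chartr("Tt", "Uu", toupper(as.character(hairpins)))
  names(seqs) <- nms
  bad <- grepl("[^ACGU]", seqs)
  if (any(bad))
    stop("hairpin sequence(s) contain non-ACGU/T characters: ",
         paste(names(seqs)[bad], collapse = ", "))
  ma <- as.data.frame(matures, stringsAsFactors = FALSE)
  ma$mirna_id <- as.character(ma$mirna_id)
  ma$hairpin_id <- as.character(ma$hairpin_id)
  ma$start <- as.integer(ma$start)
  ma$end <- as.integer(ma$end)
  ma$arm <- as.character(ma$arm)
  rownames(ma) <- NULL
  new("ReferenceSet", hairpins = Biostrings::RNAStringSet(seqs), matures = ma)
}

#' @describeIn ReferenceSet-class hairpin sequences as an `RNAStringSet`
#' @param x,object A `ReferenceSet`.
#' @export
setGeneric("hairpins", function(x) standardGeneric("hairpins"))

#' @rdname ReferenceSet-class
#' @export
setMethod("hairpins", "ReferenceSet", function(x) x@hairpins)

#' @describeIn ReferenceSet-class mature-arm annotation table
#' @export
setGeneric("matureAnnotations", function(x) standardGeneric("matureAnnotations"))

#' @rdname ReferenceSet-class
#' @export
setMethod("matureAnnotations", "ReferenceSet", function(x) x@matures)

setMethod("show", "ReferenceSet", function(object) {
  cat("ReferenceSet with", length(object@hairpins), "hairpin(s) and",
      nrow(object@matures), "mature annotation(s)\n")
  ids <- object@matures$mirna_id
  cat("  miRNAs:", paste(utils::head(ids, 6), collapse = ", "),
      if (length(ids) > 6) "..." else "", "\n")
})

#' Collapsed unique reads of one sample
#'
#' Holds the unique read sequences of one sample after adapter trimming and
#' length filtering, each with the number of times it was sequenced, plus
#' processing tallies.
#'
#' @slot sample_id Sample identifier.
#' @slot counts Named integer vector: RNA sequence -> read count (>= 1).
#' @slot n_raw Number of raw input reads.
#' @slot n_pass Number of reads surviving the length filter
#'   (`sum(counts) == n_pass`).
#' @slot n_no_adapter Number of reads in which no adapter was found.
#' @slot min_len Minimum read length applied.
#' @aliases UniqueReadSet-class
#' @seealso [collapseReads()], [preprocessFastq()]
#' @exportClass UniqueReadSet
setClass("UniqueReadSet",
         slots = c(sample_id = "character", counts = "integer",
                   n_raw = "integer", n_pass = "integer",
                   n_no_adapter = "integer", min_len = "integer"))

setValidity("UniqueReadSet", function(object) {
  msgs <- character()
  if (length(object@counts) && is.null(names(object@counts)))
    msgs <- c(msgs, "counts must be named by sequence")
  if (any(object@counts < 1L)) msgs <- c(msgs, "counts must be >= 1")
  if (sum(object@counts) != object@n_pass)
    msgs <- c(msgs, "sum(counts) must equal n_pass")
  if (length(object@counts) && any(nchar(names(object@counts)) < object@min_len))
    msgs <- c(msgs, "all sequences must be >= min_len")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

setMethod("show", "UniqueReadSet", function(object) {
  cat("UniqueReadSet '", object@sample_id, "': ",
      length(object@counts), " unique reads, ",
      object@n_pass, "/", object@n_raw, " reads passing (",
      object@n_no_adapter, " without adapter)\n", sep = "")
})

#' @describeIn UniqueReadSet-class named count vector (sequence -> count)
#' @param x,object A `UniqueReadSet`.
#' @export
setGeneric("readCounts", function(x) standardGeneric("readCounts"))

#' @rdname UniqueReadSet-class
#' @export
setMethod("readCounts", "UniqueReadSet", function(x) x@counts)

#' Negative-binomial dispersion estimates
#'
#' Common, trended and tagwise (per-feature) dispersion estimates under the
#' NB parameterization `variance = mean + phi * mean^2`.
#'
#' @slot common Single profile-likelihood dispersion shared by all features.
#' @slot trend Per-feature dispersion from a sliding window of features
#'   ranked by average abundance.
#' @slot tagwise Per-feature dispersion maximizing the feature's own profile
#'   likelihood plus `prior_weight` times the mean window likelihood.
#' @slot abundance Average log2 RPM used to order features for the trend.
#' @slot prior_weight Weight of the window likelihood in the tagwise fit.
#' @slot window Sliding-window size (number of features).
#' @aliases DispersionSet-class
#' @seealso [estimateNBDispersions()]
#' @exportClass DispersionSet
setClass("DispersionSet",
         slots = c(common = "numeric", trend = "numeric", tagwise = "numeric",
                   abundance = "numeric", prior_weight = "numeric",
                   window = "integer"))

setMethod("show", "DispersionSet", function(object) {
  cat("DispersionSet:", length(object@tagwise), "features\n")
  cat("  common phi:", format(object@common, digits = 4), "\n")
  cat("  tagwise phi range:",
      paste(format(range(object@tagwise, na.rm = TRUE), digits = 4),
            collapse = " - "),
      sprintf(" (prior weight %g, window %d)\n",
              object@prior_weight, object@window))
})

#' @describeIn DispersionSet-class common dispersion estimate
#' @param x,object A `DispersionSet`.
#' @export
setGeneric("commonDispersion", function(x) standardGeneric("commonDispersion"))

#' @rdname DispersionSet-class
#' @export
setMethod("commonDispersion", "DispersionSet", function(x) x@common)

#' @describeIn DispersionSet-class per-feature tagwise dispersions
#' @export
setGeneric("tagwiseDispersion", function(x) standardGeneric("tagwiseDispersion"))

#' @rdname DispersionSet-class
#' @export
setMethod("tagwiseDispersion", "DispersionSet", function(x) x@tagwise)

#' @describeIn DispersionSet-class per-feature trended dispersions
#' @export
setGeneric("trendDispersion", function(x) standardGeneric("trendDispersion"))

#' @rdname DispersionSet-class
#' @export
setMethod("trendDispersion", "DispersionSet", function(x) x@trend)
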