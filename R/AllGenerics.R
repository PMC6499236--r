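#' @include AllClasses.R
NULL

#' Accessors
#'
#' Small accessor generics for the package classes. \code{counts} (from
#' \pkg{BiocGenerics} conventions) returns the assay matrix of a
#' \linkS4class{GeneCountMatrix}; \code{geneIds}/\code{sampleIds} return its
#' identifiers and \code{countScale} the scale flag. \code{seedId},
#' \code{seedGenes} and \code{representative} access a
#' \linkS4class{GeneSeed}; \code{mspId}, \code{mspMembers}, \code{coreOrder}
#' and \code{mspModules} access an \linkS4class{Msp}.
#'
#' @param x an object of the documented classes.
#' @return The corresponding slot content.
#' @examples
#' m <- matrix(1:4, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' gcm <- GeneCountMatrix(m)
#' geneIds(gcm)
#' countScale(gcm)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("countScale", function(x) standardGeneric("countScale"))

#' @rdname accessors
#' @importFrom BiocGenerics counts
#' @export counts
NULL

#' @rdname accessors
#' @export
setGeneric("seedId", function(x) standardGeneric("seedId"))

#' @rdname accessors
#' @export
setGeneric("seedGenes", function(x) standardGeneric("seedGenes"))

#' @rdname accessors
#' @export
setGeneric("representative", function(x) standardGeneric("representative"))

#' @rdname accessors
#' @export
setGeneric("mspId", function(x) standardGeneric("mspId"))

#' @rdname accessors
#' @export
setGeneric("mspMembers", function(x) standardGeneric("mspMembers"))

#' @rdname accessors
#' @export
setGeneric("coreOrder", function(x) standardGeneric("coreOrder"))

#' @rdname accessors
#' @export
setGeneric("mspModules", function(x) standardGeneric("mspModules"))

#' @rdname accessors
#' @export
setMethod("geneIds", "GeneCountMatrix", function(x) rownames(x))

#' @rdname accessors
#' @export
setMethod("sampleIds", "GeneCountMatrix", function(x) colnames(x))

#' @rdname accessors
#' @export
setMethod("countScale", "GeneCountMatrix", function(x) x@countScale)

#' @rdname accessors
#' @param object a \linkS4class{GeneCountMatrix} (the \code{counts} generic's
#'   argument name).
#' @param ... ignored.
#' @export
setMethod("counts", "GeneCountMatrix",
          function(object, ...) assay(object, "counts"))

#' @rdname accessors
#' @export
setMethod("seedId", "GeneSeed", function(x) x@seedId)

#' @rdname accessors
#' @export
setMethod("seedGenes", "GeneSeed", function(x) x@geneIds)

#' @rdname accessors
#' @export
setMethod("representative", "GeneSeed", function(x) x@representative)

#' @rdname accessors
#' @export
setMethod("mspId", "Msp", function(x) x@mspId)

#' @rdname accessors
#' @export
setMethod("mspMembers", "Msp", function(x) x@members)

#' @rdname accessors
#' @export
setMethod("coreOrder", "Msp", function(x) x@coreOrder)

#' @rdname accessors
#' @export
setMethod("mspModules", "Msp", function(x) x@modules)
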