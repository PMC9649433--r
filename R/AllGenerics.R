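#' @rdname alleleNames
#' @export
setGeneric("alleleNames", function(x) standardGeneric("alleleNames"))

#' @rdname getProfile
#' @export
setGeneric("getProfile", function(x, allele) standardGeneric("getProfile"))

#' @rdname nPositions
#' @export
setGeneric("nPositions", function(x) standardGeneric("nPositions"))

#' Predict an accessibility profile from an aligned sequence
#'
#' @param object a fitted \linkS4class{SurfacePredictor}.
#' @param alignedSeq 1-letter sequence of grid length (gaps as \code{"-"}).
#' @param allele name to give the returned profile.
#' @return an \linkS4class{AlleleProfile} with provenance
#'   \code{"predicted"}; RSA defined at every non-gap position and clipped
#'   to \[0, 1.5\].
#' @export
setGeneric("predictProfile",
  function(object, alignedSeq, allele = "predicted")
    standardGeneric("predictProfile"))
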