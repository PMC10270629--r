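#' @rdname MetabolicModel-class
#' @param x,object a \linkS4class{MetabolicModel}
#' @export
setGeneric("reactions", function(x) standardGeneric("reactions"))

#' @rdname MetabolicModel-class
#' @export
setGeneric("metabolites", function(x) standardGeneric("metabolites"))

#' @rdname MetabolicModel-class
#' @export
setGeneric("stoichiometry", function(x) standardGeneric("stoichiometry"))

#' @rdname MetabolicModel-class
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname MetabolicModel-class
#' @export
setGeneric("compartments", function(x) standardGeneric("compartments"))

#' @rdname MetabolicModel-class
#' @export
setGeneric("biomassId", function(x) standardGeneric("biomassId"))

#' @rdname MetabolicModel-class
#' @export
setGeneric("objectiveId", function(x) standardGeneric("objectiveId"))
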