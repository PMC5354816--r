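#' @export
setGeneric("peaks", function(x) standardGeneric("peaks"))

#' @export
setGeneric("cellLine", function(x) standardGeneric("cellLine"))

#' @export
setGeneric("mark", function(x) standardGeneric("mark"))
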