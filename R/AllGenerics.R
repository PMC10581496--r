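#' @title Generics for phistruct containers
#' @name phistruct-generics
#' @description Accessor and analysis generics for the package's S4 classes.
#' @param x,object a phistruct object.
#' @param ... further arguments passed to methods.
#' @keywords internal
NULL

#' @describeIn phistruct-generics unit names of a network or system.
#' @export
setGeneric("unitNames", function(x) standardGeneric("unitNames"))

#' @describeIn phistruct-generics per-unit state alphabets.
#' @export
setGeneric("alphabets", function(x) standardGeneric("alphabets"))

#' @describeIn phistruct-generics transition probability matrix.
#' @export
setGeneric("tpm", function(x) standardGeneric("tpm"))

#' @describeIn phistruct-generics current state (integer indices).
#' @export
setGeneric("currentState", function(x) standardGeneric("currentState"))

#' @describeIn phistruct-generics member unit indices of a system/complex.
#' @export
setGeneric("members", function(x) standardGeneric("members"))

#' @describeIn phistruct-generics system state restricted to the members.
#' @export
setGeneric("systemState", function(x) standardGeneric("systemState"))

#' @describeIn phistruct-generics background-conditioned effect TPM.
#' @export
setGeneric("effectTpm", function(x) standardGeneric("effectTpm"))

#' @describeIn phistruct-generics background-conditioned cause TPM.
#' @export
setGeneric("causeTpm", function(x) standardGeneric("causeTpm"))

#' @describeIn phistruct-generics integrated-information value (ibits).
#' @export
setGeneric("phiValue", function(x) standardGeneric("phiValue"))

#' @describeIn phistruct-generics structure integrated information (ibits).
#' @export
setGeneric("bigPhi", function(x) standardGeneric("bigPhi"))

#' @describeIn phistruct-generics distinctions of a Phi-structure.
#' @export
setGeneric("distinctions", function(x) standardGeneric("distinctions"))

#' @describeIn phistruct-generics relations of a Phi-structure.
#' @export
setGeneric("relations", function(x) standardGeneric("relations"))

#' @describeIn phistruct-generics unfold a complex or conditioned system into
#'   its cause-effect structure.
#' @export
setGeneric("unfold", function(x, ...) standardGeneric("unfold"))

#' @describeIn phistruct-generics condense a network into disjoint complexes.
#' @export
setGeneric("condense", function(x, ...) standardGeneric("condense"))
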