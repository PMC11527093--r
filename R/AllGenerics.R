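# Generics, accessors and show() methods.

#' @rdname TetMesh-class
#' @param object,x a mesh-like object
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))
#' @rdname TetMesh-class
#' @export
setGeneric("nTets", function(x) standardGeneric("nTets"))
#' @rdname TetMesh-class
#' @export
setGeneric("nodeCoords", function(x) standardGeneric("nodeCoords"))
#' @rdname TetMesh-class
#' @export
setGeneric("tetConn", function(x) standardGeneric("tetConn"))
#' @rdname TetMesh-class
#' @export
setGeneric("boundaryTriangles", function(x) standardGeneric("boundaryTriangles"))

#' @rdname TetMesh-class
setMethod("nNodes", "TetMesh", function(x) nrow(x@nodes))
#' @rdname TetMesh-class
setMethod("nTets", "TetMesh", function(x) nrow(x@tets))
#' @rdname TetMesh-class
setMethod("nodeCoords", "TetMesh", function(x) x@nodes)
#' @rdname TetMesh-class
setMethod("tetConn", "TetMesh", function(x) x@tets)
#' @rdname TetMesh-class
setMethod("boundaryTriangles", "TetMesh", function(x) x@boundaryTris)

setMethod("show", "TetMesh", function(object) {
  cat(sprintf("%s: %d nodes, %d tets, %d boundary triangles\n",
              class(object), nNodes(object), nTets(object),
              nrow(object@boundaryTris)))
})

#' @rdname LabeledTetMesh-class
#' @param x a `LabeledTetMesh`
#' @export
setGeneric("tagNames", function(x) standardGeneric("tagNames"))
#' @rdname LabeledTetMesh-class
#' @param tag tag name
#' @export
setGeneric("tagTriangles", function(x, tag) standardGeneric("tagTriangles"))
#' @rdname LabeledTetMesh-class
#' @export
setGeneric("tagNodes", function(x, tag) standardGeneric("tagNodes"))
#' @rdname LabeledTetMesh-class
#' @export
setGeneric("landmarks", function(x) standardGeneric("landmarks"))
#' @rdname LabeledTetMesh-class
#' @export
setGeneric("fieldNames", function(x) standardGeneric("fieldNames"))
#' @rdname LabeledTetMesh-class
#' @param field field name
#' @export
setGeneric("nodeField", function(x, field) standardGeneric("nodeField"))

#' @rdname LabeledTetMesh-class
setMethod("tagNames", "LabeledTetMesh", function(x) names(x@tags))

#' @rdname LabeledTetMesh-class
setMethod("tagTriangles", "LabeledTetMesh", function(x, tag) {
  if (!tag %in% names(x@tags)) stop(sprintf("unknown tag '%s'", tag))
  x@tags[[tag]]
})

#' @rdname LabeledTetMesh-class
setMethod("tagNodes", "LabeledTetMesh", function(x, tag) {
  # node membership is derived: a node belongs to every tag of its
  # incident tagged triangles (ring tags are thin; triangle storage avoids
  # ambiguity at tag borders)
  tris <- x@boundaryTris[tagTriangles(x, tag), , drop = FALSE]
  sort(unique(as.vector(tris)))
})

#' @rdname LabeledTetMesh-class
setMethod("landmarks", "LabeledTetMesh", function(x) x@landmarks)

#' @rdname LabeledTetMesh-class
setMethod("fieldNames", "LabeledTetMesh", function(x) names(x@nodeFields))

#' @rdname LabeledTetMesh-class
setMethod("nodeField", "LabeledTetMesh", function(x, field) {
  if (!field %in% names(x@nodeFields)) stop(sprintf("unknown field '%s'", field))
  x@nodeFields[[field]]
})

setMethod("show", "LabeledTetMesh", function(object) {
  cat(sprintf("LabeledTetMesh: %d nodes, %d tets, %d boundary triangles\n",
              nNodes(object), nTets(object), nrow(object@boundaryTris)))
  cat(sprintf("  tags (%d): %s\n", length(object@tags),
              paste(names(object@tags), collapse = ", ")))
  if (length(object@landmarks)) {
    cat(sprintf("  landmarks: %s\n",
                paste(sprintf("%s=%d", names(object@landmarks),
                              object@landmarks), collapse = ", ")))
  }
  if (length(object@nodeFields)) {
    cat(sprintf("  node fields: %s\n",
                paste(names(object@nodeFields), collapse = ", ")))
  }
})

#' @rdname DistanceFieldSet-class
#' @param x a `DistanceFieldSet`
#' @export
setGeneric("distanceNames", function(x) standardGeneric("distanceNames"))
#' @rdname DistanceFieldSet-class
#' @param field field name, e.g. `"xi"` or `"la.psi_r"`
#' @export
setGeneric("distanceField", function(x, field) standardGeneric("distanceField"))
#' @rdname DistanceFieldSet-class
#' @export
setGeneric("gradientField", function(x, field) standardGeneric("gradientField"))

#' @rdname DistanceFieldSet-class
setMethod("distanceNames", "DistanceFieldSet", function(x) names(x@fields))

#' @rdname DistanceFieldSet-class
setMethod("distanceField", "DistanceFieldSet", function(x, field) {
  if (!field %in% names(x@fields)) stop(sprintf("unknown distance field '%s'", field))
  x@fields[[field]]
})

#' @rdname DistanceFieldSet-class
setMethod("gradientField", "DistanceFieldSet", function(x, field) {
  if (!field %in% names(x@gradients)) stop(sprintf("unknown distance field '%s'", field))
  x@gradients[[field]]
})

setMethod("show", "DistanceFieldSet", function(object) {
  cat(sprintf("DistanceFieldSet (%s): %d fields\n", object@mode,
              length(object@fields)))
  cat(" ", paste(names(object@fields), collapse = ", "), "\n")
})

#' @rdname BundleAssignment-class
#' @param x a `BundleAssignment`
#' @export
setGeneric("bundleLabels", function(x) standardGeneric("bundleLabels"))
#' @rdname BundleAssignment-class
setMethod("bundleLabels", "BundleAssignment", function(x) x@label)

setMethod("show", "BundleAssignment", function(object) {
  tab <- sort(table(droplevels(object@label)), decreasing = TRUE)
  cat(sprintf("BundleAssignment: %d nodes, %d bundles\n",
              length(object@label), length(tab)))
  cat(" ", paste(sprintf("%s(%d)", names(tab), tab), collapse = " "), "\n")
})

#' @rdname FiberField-class
#' @param x a `FiberField`
#' @param which one of "f", "s", "n"
#' @export
setGeneric("fiberVectors", function(x, which = "f") standardGeneric("fiberVectors"))
#' @rdname FiberField-class
setMethod("fiberVectors", "FiberField", function(x, which = "f") {
  switch(match.arg(which, c("f", "s", "n")), f = x@f, s = x@s, n = x@n)
})

setMethod("show", "FiberField", function(object) {
  cat(sprintf("FiberField: %d nodes (%d repaired-degenerate), %d bundles\n",
              nrow(object@f), sum(object@degenerate),
              nlevels(droplevels(object@bundle))))
})

#' @rdname ActivationMap-class
#' @param x an `ActivationMap`
#' @export
setGeneric("activationTimes", function(x) standardGeneric("activationTimes"))
#' @rdname ActivationMap-class
setMethod("activationTimes", "ActivationMap", function(x) x@times)

#' @rdname ActivationMap-class
#' @export
setGeneric("totalActivationTime", function(x) standardGeneric("totalActivationTime"))
#' @rdname ActivationMap-class
setMethod("totalActivationTime", "ActivationMap", function(x) {
  max(x@times[is.finite(x@times)])
})

setMethod("show", "ActivationMap", function(object) {
  cat(sprintf("ActivationMap: %d nodes, TAT = %.4g ms, %d iterations%s\n",
              length(object@times), 1e3 * totalActivationTime(object),
              object@iterations,
              if (object@converged) "" else " (NOT converged)"))
})
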