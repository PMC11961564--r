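#' Accessors for mrmediate classes
#'
#' Small accessor family: prefer these over direct slot access.
#'
#' @param object an mrmediate S4 object.
#' @return the slot value; see individual generics.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("traitName", function(object) standardGeneric("traitName"))

#' @rdname accessors
#' @export
setGeneric("records", function(object) standardGeneric("records"))

#' @rdname accessors
#' @export
setGeneric("harmonizedRows", function(object) standardGeneric("harmonizedRows"))

#' @rdname accessors
#' @export
setGeneric("exclusionLog", function(object) standardGeneric("exclusionLog"))

#' @rdname accessors
#' @export
setGeneric("mrBeta", function(object) standardGeneric("mrBeta"))

#' @rdname accessors
#' @export
setGeneric("mrSE", function(object) standardGeneric("mrSE"))

#' @rdname accessors
#' @export
setGeneric("mrPval", function(object) standardGeneric("mrPval"))

#' @rdname accessors
#' @export
setGeneric("oddsRatio", function(object) standardGeneric("oddsRatio"))

#' @rdname accessors
#' @export
setGeneric("nSnp", function(object) standardGeneric("nSnp"))

#' @rdname accessors
#' @export
setMethod("traitName", "SummaryDataset", function(object) object@traitName)

#' @rdname accessors
#' @export
setMethod("records", "SummaryDataset", function(object) object@records)

#' @rdname accessors
#' @export
setMethod("records", "InstrumentSet", function(object) object@records)

#' @rdname accessors
#' @export
setMethod("harmonizedRows", "HarmonizedSet", function(object) object@rows)

#' @rdname accessors
#' @export
setMethod("exclusionLog", "HarmonizedSet", function(object) object@exclusionLog)

#' @rdname accessors
#' @export
setMethod("mrBeta", "MRResult", function(object) object@beta)

#' @rdname accessors
#' @export
setMethod("mrSE", "MRResult", function(object) object@se)

#' @rdname accessors
#' @export
setMethod("mrPval", "MRResult", function(object) object@pval)

#' @rdname accessors
#' @export
setMethod("oddsRatio", "MRResult", function(object) object@or)

#' @rdname accessors
#' @export
setMethod("nSnp", "MRResult", function(object) object@nSnp)

#' @rdname accessors
#' @export
setMethod("nSnp", "HarmonizedSet", function(object) nrow(object@rows))

#' @rdname accessors
#' @export
setMethod("nSnp", "InstrumentSet", function(object) nrow(object@records))

setMethod("show", "SummaryDataset", function(object) {
  cat("SummaryDataset:", object@traitName, "\n")
  cat("  variants:", nrow(object@records),
      " source:", object@sourceId, "\n")
  if (nrow(object@records))
    print(head(object@records, 3))
})

setMethod("show", "HarmonizedSet", function(object) {
  cat("HarmonizedSet:", object@exposureName, "->", object@outcomeName, "\n")
  cat("  harmonized variants:", nrow(object@rows),
      " excluded:", nrow(object@exclusionLog), "\n")
})

setMethod("show", "MRResult", function(object) {
  cat(sprintf("MRResult [%s]  n_snp = %d\n", object@method, object@nSnp))
  cat(sprintf("  beta = %.4g (SE %.4g), 95%% CI [%.4g, %.4g], p = %.3g\n",
              object@beta, object@se, object@ciLow, object@ciHigh,
              object@pval))
  cat(sprintf("  OR = %.4g [%.4g, %.4g]\n",
              object@or, object@orCiLow, object@orCiHigh))
  if (object@method == "egger" && is.finite(object@intercept))
    cat(sprintf("  intercept = %.4g (SE %.4g), p = %.3g\n",
                object@intercept, object@interceptSe, object@interceptPval))
})

setMethod("show", "QResult", function(object) {
  cat(sprintf("Cochran's Q = %.4g, df = %d, p = %.3g\n",
              object@q, object@df, object@pval))
})

setMethod("show", "PressoResult", function(object) {
  cat(sprintf("MR-PRESSO: global RSS = %.4g, global p = %.3g (n_sim = %d)\n",
              object@globalRss, object@globalPval, object@nSim))
  if (nrow(object@outliers)) {
    cat("  outliers:", paste(object@outliers$snp_id, collapse = ", "), "\n")
    cat(sprintf("  distortion p = %.3g\n", object@distortionPval))
  } else cat("  no outliers flagged\n")
})

setMethod("show", "MediationResult", function(object) {
  cat(sprintf("Mediation: total = %.4g, indirect = %.4g [%.4g, %.4g] p = %.3g\n",
              object@betaTotal, object@indirect, object@indirectCiLow,
              object@indirectCiHigh, object@indirectPval))
  cat(sprintf("  direct = %.4g, proportion mediated = %s\n", object@direct,
              if (object@proportionDefined)
                sprintf("%.4g [%.4g, %.4g]", object@proportion,
                        object@proportionCiLow, object@proportionCiHigh)
              else "undefined (total effect is zero)"))
})

setMethod("show", "InstrumentSet", function(object) {
  cat("InstrumentSet for", object@exposureName, "\n")
  cat("  instruments:", nrow(object@records),
      " threshold:", format(object@thresholdUsed, digits = 3), "\n")
  cat("  stage counts:",
      paste(names(object@stageCounts), object@stageCounts,
            sep = "=", collapse = ", "), "\n")
})
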