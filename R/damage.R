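## Binary damage indicator and utilization summaries.
##
## Damage is 0 where the material holds and 1 where it failed; the
## continuous utilization u = sigma_vM / sigma_ult interpolates between the
## two, clamped to [0, 1], with u == 1 meaning failed. Failure latches: an
## element that fails at one load step stays failed afterwards.

#' Compute the element damage (utilization) field
#'
#' u = min(sigma_vM / sigma_ult, 1) per element per step; sigma_ult comes
#' from the element's group card ([PlasticCard-class]s carry it directly;
#' elastic, hyper-elastic and anisotropic cards use the compartment
#' strength, 100 MPa cortical / 10 MPa trabecular).
#'
#' @param result an [FEResult-class].
#' @param cards the [MaterialCardSet-class] the analysis used.
#' @return a [DamageField-class].
#' @export
computeDamage <- function(result, cards) {
  mesh <- result@mesh
  sigmaUlt <- vapply(as.character(mesh@elemGroup), function(g) {
    card <- cards@cards[[g]]
    if (is.null(card))
      stop("no card (hence no strength) for group ", g, call. = FALSE)
    if (is(card, "PlasticCard")) card@sigmaUltCompression
    else {
      if (is.na(card@compartment) ||
          !card@compartment %in% names(ULT_STRENGTH))
        stop("card for group ", g, " carries no compartment strength",
             call. = FALSE)
      ULT_STRENGTH[[card@compartment]]
    }
  }, numeric(1))
  u <- pmin(result@vonMises / sigmaUlt, 1)
  dim(u) <- dim(result@vonMises)
  failed <- u >= 1
  if (ncol(failed) > 1L)
    for (s in 2:ncol(failed)) failed[, s] <- failed[, s] | failed[, s - 1L]
  u <- pmax(u, failed)  # latched elements stay at utilization 1
  new("DamageField", utilization = u, failed = failed,
      failedFraction = colMeans(failed))
}

#' Per-group empirical CDFs of a damage summary
#'
#' Builds the right-continuous empirical distribution function of a
#' per-subject damage summary within each demographic group, the form
#' plotted in cumulative-damage-failure comparisons.
#'
#' @param table data.frame of per-subject summaries.
#' @param groupBy name of the grouping column (e.g. "gender", "race").
#' @param value name of the summary column (default "damage").
#' @return data.frame(group, x, F) with one row per jump point.
#' @export
damageCDF <- function(table, groupBy, value = "damage") {
  if (!groupBy %in% names(table))
    stop("unknown group key: ", groupBy, call. = FALSE)
  if (!value %in% names(table))
    stop("unknown value column: ", value, call. = FALSE)
  out <- lapply(split(table[[value]], table[[groupBy]]), function(v) {
    if (!length(v)) return(NULL)
    x <- sort(unique(v))
    data.frame(x = x, F = stats::ecdf(v)(x))
  })
  out <- out[!vapply(out, is.null, logical(1))]
  do.call(rbind, Map(function(g, df) cbind(group = g, df),
                     names(out), out)) |> `rownames<-`(NULL)
}
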