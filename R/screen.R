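#' Run a gain/loss-of-function perturbation screen
#'
#' For each row of the screen, applies the row's clamps to the network,
#' computes the attractor inventory of the perturbed dynamics, estimates the
#' phenotype probabilities by Monte Carlo random walks, and collects
#' everything in a table. Each row gets its own reproducible seed substream
#' derived from \code{(seed, row index)}.
#'
#' @param network A [BooleanNetwork-class] (typically the unperturbed model).
#' @param screen A named list; each element is a clamp spec as accepted by
#'   [applyPerturbation()], the element name being the row label.
#' @param nRuns Walks per row.
#' @param seed Master seed.
#' @param policy,fixedInputs Initial-state policy passed to
#'   [estimatePhenotypeProbabilities()]. Note that a clamped input needs no
#'   policy: its value is fixed by the clamp itself.
#' @param guard Exhaustive-regime guard for the per-row attractor
#'   computation.
#' @return A data.frame with one row per perturbation: \code{label},
#'   \code{clamps}, the four phenotype probabilities, \code{oscillatory}
#'   (whether any attractor is complex), \code{nAttractors},
#'   \code{nonConverged}, \code{nRuns} and \code{seed}. The per-row
#'   [PhenotypeEstimate-class] objects are attached as
#'   \code{attr(, "estimates")}.
#' @examples
#' net <- lncapNetwork()
#' sc <- list("miR-449a KO" = c("miR-449a" = "OFF"))
#' tab <- runPerturbationScreen(net, sc, nRuns = 100, seed = 1)
#' tab$Proliferation
#' @export
runPerturbationScreen <- function(network, screen, nRuns = 1000L, seed = 1L,
                                  policy = "uniform_all", fixedInputs = NULL,
                                  guard = .MAXSTATES) {
  stopifnot(is(network, "BooleanNetwork"), is.list(screen))
  if (is.null(names(screen)) || any(!nzchar(names(screen))))
    stop("every screen row needs a label (list names)")
  rows <- vector("list", length(screen))
  estimates <- vector("list", length(screen))
  names(estimates) <- names(screen)
  for (i in seq_along(screen)) {
    label <- names(screen)[i]
    pert <- tryCatch(applyPerturbation(network, screen[[i]]),
                     error = function(e) stop(sprintf("screen row '%s': %s",
                                                     label, conditionMessage(e)),
                                              call. = FALSE))
    rowPolicy <- policy
    rowFixed <- fixedInputs
    if (!is.null(rowFixed)) {
      rowFixed <- rowFixed[setdiff(names(rowFixed), names(pert@clamps))]
      if (length(rowFixed) == 0L) { rowFixed <- NULL; rowPolicy <- "uniform_all" }
    }
    est <- estimatePhenotypeProbabilities(
      pert, nRuns = nRuns, seed = .walkSeed(seed, i * 1000003L),
      policy = rowPolicy, fixedInputs = rowFixed, guard = guard)
    p <- phenotypeProbabilities(est)
    rows[[i]] <- data.frame(
      label = label,
      clamps = paste(sprintf("%s=%s", names(pert@clamps),
                             ifelse(pert@clamps, "ON", "OFF")), collapse = ","),
      Proliferation = p[["Proliferation"]],
      G2M_Arrest = p[["G2M_Arrest"]],
      G2M_Apoptosis = p[["G2M_Apoptosis"]],
      Undefined = p[["Undefined"]],
      oscillatory = any(est@attractors@kind == "complex"),
      nAttractors = length(est@attractors),
      nonConverged = est@nonConverged,
      nRuns = est@nRuns,
      seed = est@seed,
      stringsAsFactors = FALSE)
    estimates[[i]] <- est
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "estimates") <- estimates
  out
}

#' Preset screen: circuit perturbations under miR-449a gain of function
#'
#' The in-silico screen probing how the feedback circuits whose functionality
#' is controlled by miR-449a shift the balance between the two irradiated
#' outcomes (G2/M arrest vs apoptosis). Every row clamps miR-449a ON (E1)
#' and IR ON (the irradiated condition), plus the circuit-member clamps named
#' in the row label ("E1" = clamped ON, "KO" = clamped OFF).
#'
#' @return A named list of clamp specs suitable for
#'   [runPerturbationScreen()].
#' @examples
#' names(mir449aCircuitScreen())
#' @export
mir449aCircuitScreen <- function() {
  base <- c("miR-449a" = "ON", "IR" = "ON")
  lst <- list(
    "ATM KO / p53-MAIN E1 / Wip1 KO" = c("ATM" = "OFF", "p53-MAIN" = "ON", "Wip1" = "OFF"),
    "ATM E1 / p53-MAIN E1 / Wip1 KO" = c("ATM" = "ON", "p53-MAIN" = "ON", "Wip1" = "OFF"),
    "ATM KO / p53-MAIN E1 / Wip1 E1" = c("ATM" = "OFF", "p53-MAIN" = "ON", "Wip1" = "ON"),
    "ATM E1 / p53-MAIN E1 / Wip1 E1" = c("ATM" = "ON", "p53-MAIN" = "ON", "Wip1" = "ON"),
    "p53-MAIN E1 / Mdm2 KO"          = c("p53-MAIN" = "ON", "Mdm2" = "OFF"),
    "E2F1 KO / Sirt-1 KO"            = c("E2F1" = "OFF", "Sirt-1" = "OFF"),
    "E2F1 E1 / Sirt-1 KO"            = c("E2F1" = "ON", "Sirt-1" = "OFF"),
    "RB E1 / Mdm2 KO"                = c("RB" = "ON", "Mdm2" = "OFF"),
    "p53-MAIN E1 / 14-3-3s KO"       = c("p53-MAIN" = "ON", "14-3-3s" = "OFF"),
    "p53-MAIN E1 / 14-3-3s E1"       = c("p53-MAIN" = "ON", "14-3-3s" = "ON"))
  lapply(lst, function(x) c(x, base))
}

#' Preset screen: qualitative knockout/overexpression validations
#'
#' The qualitative perturbations used to validate the model against the
#' published LNCaP experiments: miR-449a loss of function (the cells cannot
#' arrest — only the proliferative outcome remains), miR-449a gain of
#' function (proliferation becomes impossible; arrest and apoptosis remain),
#' and c-Myc loss of function under irradiation (arrest and apoptosis).
#'
#' @return A named list of clamp specs suitable for
#'   [runPerturbationScreen()] or direct attractor analysis.
#' @examples
#' names(validationScreen())
#' @export
validationScreen <- function() {
  list(
    "miR-449a KO" = c("miR-449a" = "OFF"),
    "miR-449a E1" = c("miR-449a" = "ON"),
    "c-Myc KO under IR" = c("c-Myc" = "OFF", "IR" = "ON"))
}
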