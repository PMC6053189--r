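#' Read a boolean network from a file
#'
#' Two plain-text formats are supported. The \code{.bnet} dialect has an
#' optional \code{targets, factors} header and one \code{name, rule} line
#' per node; a node whose rule is its own name is an input. The JSON format
#' carries \code{nodes}, \code{rules} (strings), \code{inputs},
#' \code{outputs} and \code{clamps}. Errors for duplicated nodes or rules
#' referencing undeclared nodes report the offending line numbers.
#'
#' @param path File path, or the builtin model name \code{"lncap"}. Format
#'   is taken from the extension (\code{.bnet}/\code{.txt} or \code{.json})
#'   unless \code{format} is given.
#' @param format \code{"bnet"} or \code{"json"}.
#' @return A [BooleanNetwork-class].
#' @seealso [writeBooleanNetwork()]
#' @export
readBooleanNetwork <- function(path, format = NULL) {
  if (identical(path, "lncap")) return(lncapNetwork())
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, bnet = "bnet", txt = "bnet", json = "json",
                     stop("unknown model file extension '.", ext,
                          "' (use format = \"bnet\" or \"json\")"))
  }
  format <- match.arg(format, c("bnet", "json"))
  if (format == "json") {
    j <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    rules <- unlist(j$rules)
    net <- booleanNetwork(rules[j$nodes],
                          inputs = as.character(j$inputs %||% character(0)),
                          outputs = as.character(j$outputs %||% character(0)))
    if (!is.null(j$clamps) && length(j$clamps))
      net <- applyPerturbation(net, unlist(j$clamps))
    return(net)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) && grepl("^\\s*targets\\s*,\\s*factors\\s*$", lines[keep[1L]],
                            ignore.case = TRUE))
    keep <- keep[-1L]
  if (!length(keep)) stop("empty model file: ", path)
  nm <- character(0); rl <- character(0); ln <- integer(0)
  for (i in keep) {
    parts <- regmatches(lines[i], regexpr(",", lines[i]), invert = TRUE)[[1L]]
    if (length(parts) != 2L)
      stop(sprintf("%s:%d: expected 'name, rule'", path, i))
    nm <- c(nm, trimws(parts[1L])); rl <- c(rl, trimws(parts[2L])); ln <- c(ln, i)
  }
  if (anyDuplicated(nm)) {
    d <- nm[duplicated(nm)][1L]
    stop(sprintf("%s: duplicated node '%s' (lines %s)", path, d,
                 paste(ln[nm == d], collapse = ", ")))
  }
  parsed <- lapply(seq_along(nm), function(k)
    tryCatch(parseRule(rl[k]),
             error = function(e) stop(sprintf("%s:%d: %s", path, ln[k],
                                              conditionMessage(e)), call. = FALSE)))
  for (k in seq_along(parsed)) {
    bad <- setdiff(ruleVariables(parsed[[k]]), nm)
    if (length(bad))
      stop(sprintf("%s:%d: rule for '%s' references undeclared node(s): %s",
                   path, ln[k], nm[k], paste(bad, collapse = ", ")))
  }
  names(parsed) <- nm
  booleanNetwork(parsed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a boolean network to a file
#'
#' @param network A [BooleanNetwork-class].
#' @param path Output path.
#' @param format \code{"bnet"} (default; \code{targets, factors} dialect
#'   with \code{&}/\code{|}/\code{!} operators, inputs written as
#'   self-maintenance) or \code{"json"} (nodes, rule strings, inputs,
#'   outputs, clamps). Both round-trip through [readBooleanNetwork()] to an
#'   equivalent network.
#' @return Invisibly, \code{path}.
#' @export
writeBooleanNetwork <- function(network, path, format = c("bnet", "json")) {
  stopifnot(is(network, "BooleanNetwork"))
  format <- match.arg(format)
  if (format == "bnet") {
    body <- vapply(network@nodes, function(nm) {
      rule <- if (nm %in% network@inputs) nm else
        ruleToString(network@rules[[nm]], style = "symbols")
      paste0(nm, ", ", rule)
    }, "")
    writeLines(c("targets, factors", body), path)
  } else {
    obj <- list(
      nodes = network@nodes,
      rules = as.list(vapply(network@nodes, function(nm)
        if (nm %in% network@inputs) nm else ruleToString(network@rules[[nm]]), "")),
      inputs = network@inputs,
      outputs = network@outputs,
      clamps = as.list(network@clamps))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Attractors as a stable-state table
#'
#' Lays attractors out as a table of node values: one row per member state
#' (fixed points contribute a single row), node columns ordered inputs
#' first, internal nodes, then the phenotype outputs right-most — the usual
#' stable-state presentation of logical models.
#'
#' @param attractors An [AttractorSet-class].
#' @return A data.frame with columns \code{attractor}, \code{kind},
#'   \code{phenotype}, then one 0/1 column per node.
#' @examples
#' attractorTable(findAttractors(lncapNetwork()))
#' @export
attractorTable <- function(attractors) {
  stopifnot(is(attractors, "AttractorSet"))
  net <- attractors@network
  colOrder <- c(net@inputs, setdiff(net@nodes, c(net@inputs, net@outputs)),
                net@outputs)
  rows <- lapply(seq_along(attractors@states), function(i) {
    m <- .decodeStates(attractors@states[[i]], net@nodes)[, colOrder, drop = FALSE]
    data.frame(attractor = i, kind = attractors@kind[i],
               phenotype = attractors@phenotype[i],
               matrix(as.integer(m), nrow = nrow(m),
                      dimnames = list(NULL, colOrder)),
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Serialize results to CSV or JSON
#'
#' Writes a result object with a stable column order; the JSON form embeds
#' the configuration needed to regenerate the numbers (seed, policy, clamps,
#' number of runs), making results files self-describing.
#'
#' @param x A screen table (data.frame), [AttractorSet-class] or
#'   [PhenotypeEstimate-class].
#' @param path Output path.
#' @param format \code{"csv"} or \code{"json"}.
#' @param digits Fixed number of decimal digits for probabilities in CSV
#'   output.
#' @return Invisibly, \code{path}.
#' @export
writeResults <- function(x, path, format = c("csv", "json"), digits = 6L) {
  format <- match.arg(format)
  if (is(x, "AttractorSet")) x <- attractorTable(x)
  if (is(x, "PhenotypeEstimate")) {
    est <- x
    x <- data.frame(phenotype = names(est@counts), count = as.integer(est@counts),
                    proportion = as.numeric(phenotypeProbabilities(est)),
                    stringsAsFactors = FALSE)
    attr(x, "config") <- list(nRuns = est@nRuns, seed = est@seed,
                              nonConverged = est@nonConverged, policy = est@policy)
  }
  if (!is.data.frame(x)) stop("unsupported result type: ", class(x)[1L])
  if (format == "csv") {
    y <- x
    num <- vapply(y, is.double, TRUE)
    y[num] <- lapply(y[num], function(v) formatC(v, digits = digits, format = "f"))
    utils::write.csv(y, path, row.names = FALSE, quote = TRUE)
  } else {
    cfg <- attr(x, "config")
    if (is.null(cfg)) {
      est <- attr(x, "estimates")
      if (!is.null(est) && length(est))
        cfg <- list(nRuns = est[[1L]]@nRuns, policy = est[[1L]]@policy$policy)
    }
    jsonlite::write_json(list(results = x, config = cfg), path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
  }
  invisible(path)
}
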