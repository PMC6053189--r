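#' The LNCaP G2/M checkpoint network
#'
#' The 21-node logical model of G2/M checkpoint regulation in LNCaP prostate
#' carcinoma cells under ionizing radiation. The sole input is \code{IR}
#' (ionizing radiation). DNA damage activates the ATM/ATR kinases and, via
#' p53 (split into \code{p53-MAIN}, \code{p53-Arrest} and \code{p53-Killer}
#' to capture its phosphorylation states), drives the checkpoint readouts;
#' \code{miR-449a}, induced by IR, represses \code{c-Myc}, \code{E2F1},
#' \code{Cdc25ABC} and \code{Sirt-1}. The three readout nodes are
#' \code{Proliferation}, \code{G2/M-Arrest} and \code{G2/M-Apoptosis}.
#'
#' @return A [BooleanNetwork-class] with 21 nodes, input \code{IR} and the
#'   three phenotype outputs.
#' @examples
#' net <- lncapNetwork()
#' networkRules(net)[["ATR"]]
#' @export
lncapNetwork <- function() {
  rules <- c(
    "IR"             = "IR",
    "ATM"            = "IR AND (NOT Wip1 OR E2F1)",
    "ATR"            = "IR",
    "miR-449a"       = "IR",
    "Sirt-1"         = "E2F1 OR NOT miR-449a",
    "p53-MAIN"       = "(ATM OR ATR OR (E2F1 AND 14-3-3s)) AND NOT Mdm2",
    "Mdm2"           = "(NOT Wip1 OR p53-MAIN OR RB) AND NOT ATM AND NOT ATR",
    "p53-Arrest"     = "(p53-MAIN:1 OR NOT p53-INP1) AND NOT p53-Killer AND NOT Sirt-1",
    "p53-Killer"     = "NOT p53-Arrest AND (NOT Sirt-1 OR NOT Wip1) AND p53-MAIN",
    "p53-INP1"       = "p53-Arrest OR p53-Killer",
    "Wip1"           = "p53-Arrest",
    "p21"            = "(p53-Arrest OR p53-Killer) AND NOT c-Myc",
    "14-3-3s"        = "p53-Arrest OR p53-Killer",
    "c-Myc"          = "(E2F1 OR NOT RB) AND NOT miR-449a",
    "E2F1"           = "(NOT RB AND ((ATM AND ATR AND NOT miR-449a) OR NOT Sirt-1)) OR c-Myc OR Cdc25ABC",
    "RB"             = "NOT Mdm2 AND NOT Cdc25ABC AND NOT Sirt-1",
    "Cdc25ABC"       = "(NOT miR-449a OR c-Myc) AND NOT ATM AND NOT ATR AND NOT 14-3-3s",
    "Cdc2-CycB"      = "Cdc25ABC OR (NOT p21 AND NOT 14-3-3s)",
    "Proliferation"  = "NOT p53-MAIN AND (Cdc2-CycB OR E2F1)",
    "G2/M-Arrest"    = "p21 OR 14-3-3s",
    "G2/M-Apoptosis" = "p53-Killer")
  net <- booleanNetwork(rules, inputs = "IR",
                        outputs = c("Proliferation", "G2/M-Arrest", "G2/M-Apoptosis"))
  stopifnot(length(net@nodes) == 21L, identical(net@inputs, "IR"))
  net
}
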