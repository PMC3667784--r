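## Shared fixtures: tiny hand-specified networks built through the public
## species-table + reaction-table contract, used as integration oracles.

## A + B <-> C (A, C membrane-resident so composition bookkeeping holds)
tiny_binding_network <- function(kon = 0.02, koff = 0.05) {
  species <- data.frame(
    name = c("A", "B", "C"),
    m14 = c(1, 0, 1), t2 = c(0, 1, 1), m2 = 0, m2act = 0, ecm = 0,
    location = c("membrane", "solution", "membrane"),
    pool = NA_character_, activity_weight = c(1, 0, 0),
    stringsAsFactors = FALSE)
  tab <- data.frame(
    reactants = c("A + B", "C"),
    products = c("C", "A + B"),
    k = c(kon, koff), tag = c("binding", "dissociation"),
    type = "mass_action", pool = NA, mf0 = NA,
    stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".tsv")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  readReactionTable(path, species)
}

## E + S <-> ES -> E (substrate consumed): explicit enzyme-substrate cycle
tiny_enzyme_network <- function(kon = 0.01, koff = 0.1, kcat = 0.5) {
  species <- data.frame(
    name = c("E", "S", "ES"),
    m14 = c(1, 0, 1), t2 = 0, m2 = 0, m2act = 0, ecm = c(0, 1, 1),
    location = c("membrane", "solution", "membrane"),
    pool = NA_character_, activity_weight = c(1, 0, 0),
    stringsAsFactors = FALSE)
  tab <- data.frame(
    reactants = c("E + S", "ES", "ES"),
    products = c("ES", "E + S", "E"),
    k = c(kon, koff, kcat),
    tag = c("ecm_binding", "dissociation", "ecm_cleavage"),
    type = "mass_action", pool = NA, mf0 = NA,
    stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".tsv")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  readReactionTable(path, species)
}

## X -> (removed), for closed-form decay checks; species named ECM so the
## tau-half metric applies directly
tiny_decay_network <- function(k = 0.1) {
  species <- data.frame(
    name = "ECM", m14 = 0, t2 = 0, m2 = 0, m2act = 0, ecm = 1,
    location = "solution", pool = NA_character_, activity_weight = 0,
    stringsAsFactors = FALSE)
  tab <- data.frame(
    reactants = "ECM", products = "", k = k, tag = "ecm_cleavage",
    type = "mass_action", pool = NA, mf0 = NA, stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".tsv")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  readReactionTable(path, species)
}

## default-parameter shorthand used across tests
par0 <- defaultKineticParameters()
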