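# Deterministic synthetic-database builders. Each builder creates an
# embedded SQLite file and returns a GroundTruth object: the exact in-memory
# copy of every inserted row, per table. Tests and oracles assert mapping
# output against the GroundTruth alone, never by re-querying the database.

#' Specify a synthetic fixture database
#'
#' One seeded generator drives all random draws, so identical specs yield
#' identical database content and identical query answers. The defaults
#' describe a small protein-interaction toy database: interaction rows with
#' a type and a confirmed flag, per-protein physicochemical features (mass
#' in Da, isoelectric point), and scored predicted interactions. The extra
#' fields parameterize the three case-study builders.
#'
#' @param seed integer RNG seed.
#' @param nProteins number of proteins (ids \code{P1..Pn}).
#' @param nInteractions rows in \code{interactions}.
#' @param confirmedFraction fraction of interactions flagged \code{'Y'}.
#' @param nPredictions rows in \code{predictedInteractions}.
#' @param nDomains,membershipsPerProtein protein-domain case parameters.
#' @param nMolecules,nReactions reaction case parameters.
#' @param nOntologies,nTermsPerOntology,branching term-hierarchy case
#'   parameters.
#' @return a \code{FixtureSpec} (validated list).
#' @export
fixtureSpec <- function(seed = 1L, nProteins = 20L, nInteractions = 40L,
                        confirmedFraction = 0.5, nPredictions = 30L,
                        nDomains = 6L, membershipsPerProtein = 2L,
                        nMolecules = 10L, nReactions = 6L,
                        nOntologies = 3L, nTermsPerOntology = 15L,
                        branching = 3L) {
  spec <- list(seed = as.integer(seed), nProteins = as.integer(nProteins),
               nInteractions = as.integer(nInteractions),
               confirmedFraction = confirmedFraction,
               nPredictions = as.integer(nPredictions),
               nDomains = as.integer(nDomains),
               membershipsPerProtein = as.integer(membershipsPerProtein),
               nMolecules = as.integer(nMolecules),
               nReactions = as.integer(nReactions),
               nOntologies = as.integer(nOntologies),
               nTermsPerOntology = as.integer(nTermsPerOntology),
               branching = as.integer(branching))
  if (spec$confirmedFraction < 0 || spec$confirmedFraction > 1)
    usageError("confirmedFraction must be in [0, 1]")
  if (any(unlist(spec[c("nProteins", "nOntologies", "nTermsPerOntology",
                        "branching")]) < 1L))
    usageError("fixture sizes must be positive")
  structure(spec, class = "FixtureSpec")
}

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

newDb <- function(path, overwrite) {
  if (file.exists(path)) {
    if (!overwrite)
      ioError(sprintf("refusing to overwrite existing database: %s", path))
    unlink(path)
  }
  DBI::dbConnect(RSQLite::SQLite(), path)
}

groundTruth <- function(spec, tables) {
  structure(list(spec = spec, tables = tables), class = "GroundTruth")
}

#' @export
print.GroundTruth <- function(x, ...) {
  cat("GroundTruth (seed", x$spec$seed, "):\n")
  for (nm in names(x$tables))
    cat(sprintf("  %s: %d row(s)\n", nm, nrow(x$tables[[nm]])))
  invisible(x)
}

#' Write a ground-truth sidecar document
#'
#' JSON rendering of every inserted row, for external inspection of a
#' fixture database.
#'
#' @param gt a \code{GroundTruth}.
#' @param path output JSON file.
#' @return invisibly the path.
#' @export
writeGroundTruth <- function(gt, path) {
  jsonlite::write_json(list(spec = unclass(gt$spec), tables = gt$tables),
                       path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Build the toy protein-interaction database
#'
#' Creates \code{interactions(protn1, protn2, intType, confirmed)},
#' \code{features(protein, mass, pI)} (one row per protein) and
#' \code{predictedInteractions(protn1, protn2, intType, score)}. The
#' confirmed flag is \code{'Y'} for exactly
#' \code{round(confirmedFraction * nInteractions)} rows. Self-interactions
#' and duplicate pairs occur at low probability, deliberately exercising the
#' mapper's merge path. About half of the predictions reuse pairs from
#' \code{interactions} (so edge enrichment finds matches); the rest are
#' random pairs (so expansion adds new neighbors). All four documented
#' example queries run against this database.
#'
#' @param spec a [fixtureSpec()].
#' @param path SQLite file to create.
#' @param overwrite allow replacing an existing file.
#' @return a \code{GroundTruth} with tables \code{interactions},
#'   \code{features}, \code{predictedInteractions}.
#' @export
buildToyDb <- function(spec, path, overwrite = FALSE) {
  stopifnot(inherits(spec, "FixtureSpec"))
  tables <- withSeed(spec$seed, {
    proteins <- paste0("P", seq_len(spec$nProteins))
    intTypes <- c("pp", "pd", "genetic")
    p1 <- sample(proteins, spec$nInteractions, replace = TRUE)
    p2 <- sample(proteins, spec$nInteractions, replace = TRUE)
    self <- stats::runif(spec$nInteractions) < 0.05
    p2[self] <- p1[self]
    confirmed <- rep("N", spec$nInteractions)
    nY <- round(spec$confirmedFraction * spec$nInteractions)
    confirmed[sample(seq_len(spec$nInteractions), nY)] <- "Y"
    interactions <- data.frame(
      protn1 = p1, protn2 = p2,
      intType = sample(intTypes, spec$nInteractions, replace = TRUE),
      confirmed = confirmed, stringsAsFactors = FALSE)
    features <- data.frame(
      protein = proteins,
      mass = round(stats::runif(spec$nProteins, 5e3, 1.5e5), 1),
      pI = round(stats::runif(spec$nProteins, 3, 12), 2),
      stringsAsFactors = FALSE)
    nFromKnown <- min(spec$nPredictions %/% 2L, spec$nInteractions)
    known <- sample(seq_len(spec$nInteractions), nFromKnown)
    nNew <- spec$nPredictions - nFromKnown
    predictedInteractions <- data.frame(
      protn1 = c(interactions$protn1[known],
                 sample(proteins, nNew, replace = TRUE)),
      protn2 = c(interactions$protn2[known],
                 sample(proteins, nNew, replace = TRUE)),
      intType = sample(intTypes, spec$nPredictions, replace = TRUE),
      score = round(stats::runif(spec$nPredictions), 3),
      stringsAsFactors = FALSE)
    list(interactions = interactions, features = features,
         predictedInteractions = predictedInteractions)
  })
  db <- newDb(path, overwrite)
  on.exit(DBI::dbDisconnect(db))
  DBI::dbExecute(db, "CREATE TABLE interactions (protn1 TEXT, protn2 TEXT, intType TEXT, confirmed TEXT)")
  DBI::dbExecute(db, "CREATE TABLE features (protein TEXT, mass REAL, pI REAL)")
  DBI::dbExecute(db, "CREATE TABLE predictedInteractions (protn1 TEXT, protn2 TEXT, intType TEXT, score REAL)")
  for (nm in names(tables))
    DBI::dbWriteTable(db, nm, tables[[nm]], append = TRUE)
  groundTruth(spec, tables)
}

#' Build the protein-domain membership database
#'
#' Three tables — \code{proteins(protein, nodeType)},
#' \code{domains(domain, nodeType, description)} and
#' \code{membership(protein, domain)} — such that a single three-table join
#' yields a bipartite protein-domain edge list with a node-type attribute on
#' both endpoints. Each protein is a member of
#' \code{membershipsPerProtein} distinct domains.
#'
#' @inheritParams buildToyDb
#' @return a \code{GroundTruth} with tables \code{proteins}, \code{domains},
#'   \code{membership}.
#' @export
buildProteinDomainDb <- function(spec, path, overwrite = FALSE) {
  stopifnot(inherits(spec, "FixtureSpec"))
  tables <- withSeed(spec$seed + 101L, {
    prot <- paste0("P", seq_len(spec$nProteins))
    dom <- paste0("D", seq_len(spec$nDomains))
    k <- min(spec$membershipsPerProtein, spec$nDomains)
    membership <- do.call(rbind, lapply(prot, function(p) {
      data.frame(protein = p, domain = sample(dom, k),
                 stringsAsFactors = FALSE)
    }))
    list(proteins = data.frame(protein = prot, nodeType = "protein",
                               stringsAsFactors = FALSE),
         domains = data.frame(domain = dom, nodeType = "domain",
                              description = paste("domain family", dom),
                              stringsAsFactors = FALSE),
         membership = membership)
  })
  db <- newDb(path, overwrite)
  on.exit(DBI::dbDisconnect(db))
  DBI::dbExecute(db, "CREATE TABLE proteins (protein TEXT, nodeType TEXT)")
  DBI::dbExecute(db, "CREATE TABLE domains (domain TEXT, nodeType TEXT, description TEXT)")
  DBI::dbExecute(db, "CREATE TABLE membership (protein TEXT, domain TEXT)")
  for (nm in names(tables))
    DBI::dbWriteTable(db, nm, tables[[nm]], append = TRUE)
  groundTruth(spec, tables)
}

#' Build the molecule-reaction database
#'
#' Tables \code{molecules}, \code{reactions},
#' \code{participation(molecule, reaction, role)} with roles
#' \code{substrate}/\code{product}, and a shared
#' \code{descriptions(id, description)} table, supporting a create query
#' (the bipartite participation network) plus one enrichment query that
#' loads descriptions for molecule and reaction nodes alike.
#'
#' @inheritParams buildToyDb
#' @return a \code{GroundTruth} with tables \code{molecules},
#'   \code{reactions}, \code{participation}, \code{descriptions}.
#' @export
buildReactionDb <- function(spec, path, overwrite = FALSE) {
  stopifnot(inherits(spec, "FixtureSpec"))
  tables <- withSeed(spec$seed + 202L, {
    mol <- paste0("M", seq_len(spec$nMolecules))
    rxn <- paste0("R", seq_len(spec$nReactions))
    participation <- do.call(rbind, lapply(rxn, function(r) {
      parts <- sample(mol, min(3L, spec$nMolecules))
      data.frame(molecule = parts, reaction = r,
                 role = c("substrate", "substrate", "product")[seq_along(parts)],
                 stringsAsFactors = FALSE)
    }))
    list(molecules = data.frame(molecule = mol, stringsAsFactors = FALSE),
         reactions = data.frame(reaction = rxn, stringsAsFactors = FALSE),
         participation = participation,
         descriptions = data.frame(
           id = c(mol, rxn),
           description = c(paste("small molecule", mol),
                           paste("enzymatic reaction", rxn)),
           stringsAsFactors = FALSE))
  })
  db <- newDb(path, overwrite)
  on.exit(DBI::dbDisconnect(db))
  DBI::dbExecute(db, "CREATE TABLE molecules (molecule TEXT)")
  DBI::dbExecute(db, "CREATE TABLE reactions (reaction TEXT)")
  DBI::dbExecute(db, "CREATE TABLE participation (molecule TEXT, reaction TEXT, role TEXT)")
  DBI::dbExecute(db, "CREATE TABLE descriptions (id TEXT, description TEXT)")
  for (nm in names(tables))
    DBI::dbWriteTable(db, nm, tables[[nm]], append = TRUE)
  groundTruth(spec, tables)
}

#' Build the ontology-term hierarchy database
#'
#' Tables \code{terms(term, ontology)} and
#' \code{termRelations(child, parent, relType)} forming
#' \code{nOntologies} disjoint rooted trees: term \code{k} of ontology
#' \code{o} is \code{T<o>_<k>}, and the parent of term \code{k > 1} is term
#' \code{floor((k - 2) / branching) + 1} of the same ontology. The mapped
#' parent-link network therefore has exactly \code{nOntologies} weakly
#' connected components, each acyclic.
#'
#' @inheritParams buildToyDb
#' @return a \code{GroundTruth} with tables \code{terms},
#'   \code{termRelations}.
#' @export
buildTermDb <- function(spec, path, overwrite = FALSE) {
  stopifnot(inherits(spec, "FixtureSpec"))
  rows <- list(); trows <- list()
  for (o in seq_len(spec$nOntologies)) {
    term <- sprintf("T%d_%d", o, seq_len(spec$nTermsPerOntology))
    trows[[o]] <- data.frame(term = term, ontology = paste0("ontology", o),
                             stringsAsFactors = FALSE)
    if (spec$nTermsPerOntology > 1L) {
      k <- 2:spec$nTermsPerOntology
      rows[[o]] <- data.frame(child = term[k],
                              parent = term[(k - 2L) %/% spec$branching + 1L],
                              relType = "is_a", stringsAsFactors = FALSE)
    }
  }
  tables <- list(terms = do.call(rbind, trows),
                 termRelations = do.call(rbind, rows))
  db <- newDb(path, overwrite)
  on.exit(DBI::dbDisconnect(db))
  DBI::dbExecute(db, "CREATE TABLE terms (term TEXT, ontology TEXT)")
  DBI::dbExecute(db, "CREATE TABLE termRelations (child TEXT, parent TEXT, relType TEXT)")
  for (nm in names(tables))
    DBI::dbWriteTable(db, nm, tables[[nm]], append = TRUE)
  groundTruth(spec, tables)
}

#' The four documented example queries for the toy database
#'
#' One query per mode of operation: create a confirmed-interaction network,
#' load per-protein features as node attributes, load prediction type and
#' score onto existing edges, and expand the network with predicted
#' neighbors of seed nodes.
#'
#' @return named character vector with entries \code{create},
#'   \code{node_attrs}, \code{edge_attrs}, \code{expand}.
#' @export
toyExampleQueries <- function() {
  c(create = "SELECT protn1, protn2, intType, confirmed FROM interactions WHERE confirmed = 'Y'",
    node_attrs = "SELECT protein, mass, pI FROM features WHERE protein = ?",
    edge_attrs = "SELECT protn1, protn2, intType, score FROM predictedInteractions WHERE protn1 = ? AND protn2 = ?",
    expand = "SELECT protn2, intType, score FROM predictedInteractions WHERE protn1 = ?")
}
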