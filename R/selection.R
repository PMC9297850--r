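#' Resolve an atom selection expression
#'
#' A small selection language over the atom table. Primaries are
#' `chain`, `resid`, `resname`, `name`, `element`, `serial`, each followed
#' by one or more values (`resid` also accepts ranges `241:245`), plus the
#' bare keywords `all`, `hetero`, `protein`, `backbone` and `sidechain`.
#' Primaries combine with `and`, `or`, `not` and parentheses.
#'
#' Resolution is order-stable: indices are returned sorted by topology
#' position, without duplicates. An expression that matches nothing returns
#' an empty integer vector (this is legal, not an error).
#'
#' @param structure An `md_structure` (or the topology of an ensemble).
#' @param expr Selection expression string, e.g.
#'   `"resid 171 and chain A"`, `"element H and resid 95"`,
#'   `"name H41 H42 or name C4"`.
#' @return Sorted integer vector of atom row indices (1-based).
#' @export
select_atoms <- function(structure, expr) {
  if (inherits(structure, "md_ensemble")) structure <- structure$topology
  toks <- tokenize_selection(expr)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  mask <- parse_or(st, structure)
  if (st$pos <= length(st$toks)) {
    abort_config(sprintf("Selection syntax error near '%s' in \"%s\".",
                         st$toks[st$pos], expr))
  }
  which(mask)
}

BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT", "H", "H1", "H2", "H3", "HA",
                    "HA2", "HA3")

tokenize_selection <- function(expr) {
  if (!is.character(expr) || length(expr) != 1 || is.na(expr) || trimws(expr) == "") {
    abort_config("Selection expression must be a non-empty string.")
  }
  expr <- gsub("\\(", " ( ", expr)
  expr <- gsub("\\)", " ) ", expr)
  toks <- strsplit(trimws(expr), "\\s+")[[1]]
  if (length(toks) == 0) abort_config("Empty selection expression.")
  toks
}

peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_
advance <- function(st) { st$pos <- st$pos + 1L; st$toks[st$pos - 1L] }

SEL_KEYWORDS <- c("chain", "resid", "resname", "name", "element", "serial")
SEL_BARE <- c("all", "hetero", "protein", "backbone", "sidechain", "hydrogen")
SEL_OPS <- c("and", "or", "not", "(", ")", "&", "|", "!")

parse_or <- function(st, atoms) {
  mask <- parse_and(st, atoms)
  while (!is.na(peek(st)) && tolower(peek(st)) %in% c("or", "|")) {
    advance(st)
    mask <- mask | parse_and(st, atoms)
  }
  mask
}

parse_and <- function(st, atoms) {
  mask <- parse_factor(st, atoms)
  while (!is.na(peek(st)) && tolower(peek(st)) %in% c("and", "&")) {
    advance(st)
    mask <- mask & parse_factor(st, atoms)
  }
  mask
}

parse_factor <- function(st, atoms) {
  tok <- peek(st)
  if (is.na(tok)) abort_config("Selection ended unexpectedly.")
  low <- tolower(tok)
  if (low %in% c("not", "!")) {
    advance(st)
    return(!parse_factor(st, atoms))
  }
  if (tok == "(") {
    advance(st)
    mask <- parse_or(st, atoms)
    if (is.na(peek(st)) || peek(st) != ")") abort_config("Unbalanced parenthesis in selection.")
    advance(st)
    return(mask)
  }
  parse_primary(st, atoms)
}

parse_primary <- function(st, atoms) {
  tok <- advance(st)
  low <- tolower(tok)
  if (low %in% SEL_BARE) {
    return(switch(low,
      all = rep(TRUE, nrow(atoms)),
      hetero = atoms$is_hetero,
      protein = !atoms$is_hetero,
      backbone = !atoms$is_hetero & atoms$name %in% BACKBONE_NAMES,
      sidechain = !atoms$is_hetero & !atoms$name %in% BACKBONE_NAMES,
      hydrogen = atoms$element == "H"
    ))
  }
  if (!low %in% SEL_KEYWORDS) {
    abort_config(sprintf("Unknown selection keyword '%s'.", tok))
  }
  vals <- character()
  while (!is.na(peek(st)) &&
         !tolower(peek(st)) %in% c(SEL_KEYWORDS, SEL_BARE, "and", "or", "not") &&
         !peek(st) %in% c("(", ")", "&", "|", "!")) {
    vals <- c(vals, advance(st))
  }
  if (length(vals) == 0) {
    abort_config(sprintf("Selection keyword '%s' needs at least one value.", tok))
  }
  if (low %in% c("resid", "serial")) {
    nums <- integer(0)
    for (v in vals) {
      if (grepl("^-?[0-9]+[:-][0-9]+$", v)) {
        parts <- as.integer(strsplit(v, "[:-]")[[1]])
        nums <- c(nums, seq(parts[1], parts[2]))
      } else {
        n <- suppressWarnings(as.integer(v))
        if (is.na(n)) abort_config(sprintf("Bad numeric value '%s' for '%s'.", v, tok))
        nums <- c(nums, n)
      }
    }
    col <- atoms[[low]]
    return(col %in% nums)
  }
  col <- atoms[[switch(low, chain = "chain", resname = "resname",
                       name = "name", element = "element")]]
  col %in% vals
}
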