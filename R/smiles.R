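#' @title Molecular graphs from SMILES
#' @description
#' A small self-contained SMILES reader/writer producing the molecular-graph
#' representation the opto-electronic filter operates on.  It supports the
#' constructs that occur in toolkit-canonical SMILES: the organic subset,
#' bracket atoms with charge/H-count/isotope, aromatic lowercase atoms,
#' branches, ring closures (including `%nn`), dot-separated fragments and
#' directional bonds (read as single).  Stereochemistry is ignored: none of
#' the filter rules depend on it.
#' @name smiles-graph
NULL

# atomic numbers for the elements the filter can meet; anything absent is
# still parseable (composition rejects it) but has no electron count
.ATOMIC_NUMBER <- c(
  H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8, F = 9, Ne = 10,
  Na = 11, Mg = 12, Al = 13, Si = 14, P = 15, S = 16, Cl = 17, Ar = 18,
  K = 19, Ca = 20, Sc = 21, Ti = 22, V = 23, Cr = 24, Mn = 25, Fe = 26,
  Co = 27, Ni = 28, Cu = 29, Zn = 30, Ga = 31, Ge = 32, As = 33, Se = 34,
  Br = 35, Kr = 36, Rb = 37, Sr = 38, Y = 39, Zr = 40, Nb = 41, Mo = 42,
  Tc = 43, Ru = 44, Rh = 45, Pd = 46, Ag = 47, Cd = 48, In = 49, Sn = 50,
  Sb = 51, Te = 52, I = 53, Xe = 54, Cs = 55, Ba = 56, La = 57, Ce = 58,
  W = 74, Re = 75, Os = 76, Ir = 77, Pt = 78, Au = 79, Hg = 80, Tl = 81,
  Pb = 82, Bi = 83
)

# default valences used for implicit-hydrogen assignment (organic subset)
.VALENCES <- list(
  B = 3, C = 4, N = 3, O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1, Se = c(2, 4, 6), Si = 4
)

.ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

#' Parse a SMILES string into a molecular graph
#'
#' @param smiles a single SMILES string.
#' @return an object of class `uvvis_mol`: a list with `atoms`
#'   (data.frame: `element`, `aromatic`, `charge`, `hcount`) and `bonds`
#'   (data.frame: `from`, `to`, `order`, `aromatic`).  `hcount` is the total
#'   hydrogen count per heavy atom (explicit bracket count, or implicit by
#'   the usual valence rules).
#' @examples
#' m <- parse_smiles("c1ccccc1")
#' nrow(m$atoms)  # 6
#' @export
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, !is.na(smiles))
  s <- gsub("\\s", "", smiles)
  if (!nzchar(s)) stop_uvvis("empty SMILES", "uvvisdb_parse_error")

  element <- character(); aromatic <- logical()
  charge <- integer(); hexp <- integer()  # hexp: explicit bracket H or NA
  from <- integer(); to <- integer(); order <- numeric(); barom <- logical()

  add_atom <- function(el, arom, chg = 0L, h = NA_integer_) {
    element[length(element) + 1L] <<- el
    aromatic[length(aromatic) + 1L] <<- arom
    charge[length(charge) + 1L] <<- as.integer(chg)
    hexp[length(hexp) + 1L] <<- h
    length(element)
  }
  add_bond <- function(a, b, ord) {
    if (is.na(ord)) {                      # default bond
      if (aromatic[a] && aromatic[b]) ord <- 1.5 else ord <- 1
    }
    from[length(from) + 1L] <<- a
    to[length(to) + 1L] <<- b
    order[length(order) + 1L] <<- if (ord == 1.5) 1 else ord
    barom[length(barom) + 1L] <<- (ord == 1.5)
  }

  i <- 1L; n <- nchar(s)
  prev <- NA_integer_
  pending <- NA_real_      # bond order queued by an explicit bond symbol
  stack <- integer()
  rings <- list()          # digit -> list(atom, order)

  peek <- function(k = 0L) if (i + k <= n) substr(s, i + k, i + k) else ""

  while (i <= n) {
    ch <- peek()
    if (ch == "(") {
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]; i <- i + 1L
    } else if (ch %in% c("-", "/", "\\")) {
      pending <- 1; i <- i + 1L
    } else if (ch == "=") {
      pending <- 2; i <- i + 1L
    } else if (ch == "#") {
      pending <- 3; i <- i + 1L
    } else if (ch == ":") {
      pending <- 1.5; i <- i + 1L
    } else if (ch == ".") {
      prev <- NA_integer_; pending <- NA_real_; i <- i + 1L
    } else if (grepl("[0-9]", ch) || ch == "%") {
      if (ch == "%") { id <- substr(s, i + 1L, i + 2L); i <- i + 3L }
      else { id <- ch; i <- i + 1L }
      if (is.null(rings[[id]])) {
        rings[[id]] <- list(atom = prev, order = pending)
      } else {
        op <- rings[[id]]
        ord <- if (!is.na(pending)) pending else op$order
        add_bond(op$atom, prev, if (is.na(ord)) NA_real_ else ord)
        rings[[id]] <- NULL
      }
      pending <- NA_real_
    } else if (ch == "[") {
      close <- regexpr("]", substr(s, i, n), fixed = TRUE)
      if (close < 0) stop_uvvis("unclosed bracket atom in SMILES", "uvvisdb_parse_error")
      body <- substr(s, i + 1L, i + close - 2L)
      i <- i + close
      m <- regmatches(body, regexec(
        "^([0-9]*)([A-Za-z][a-z]?|\\*)(@(?:TH|AL|SP|TB|OH)[0-9]+|@{1,2})?(H[0-9]*)?([+-][0-9]*|\\++|-+)?(:[0-9]+)?$",
        body, perl = TRUE))[[1]]
      if (length(m) == 0L) {
        stop_uvvis(sprintf("unparseable bracket atom '[%s]'", body), "uvvisdb_parse_error")
      }
      sym <- m[3]
      arom <- sym == tolower(sym) && sym != "*"
      el <- if (sym == "*") "*" else paste0(toupper(substr(sym, 1, 1)), substring(sym, 2))
      hh <- m[5]
      h <- if (!nzchar(hh)) 0L else if (hh == "H") 1L else as.integer(substring(hh, 2))
      cc <- m[6]
      chg <- if (!nzchar(cc)) 0L
      else if (cc %in% c("+", "-")) ifelse(cc == "+", 1L, -1L)
      else if (grepl("^\\++$", cc)) nchar(cc)
      else if (grepl("^-+$", cc)) -nchar(cc)
      else as.integer(paste0(substr(cc, 1, 1), substring(cc, 2)))
      a <- add_atom(el, arom, chg, h)
      if (!is.na(prev)) add_bond(prev, a, pending)
      prev <- a; pending <- NA_real_
    } else {
      # organic-subset atom, aromatic lowercase or aliphatic (2-letter first)
      two <- paste0(ch, peek(1L))
      if (two %in% c("Cl", "Br")) {
        a <- add_atom(two, FALSE); i <- i + 2L
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
        a <- add_atom(ch, FALSE); i <- i + 1L
      } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
        a <- add_atom(toupper(ch), TRUE); i <- i + 1L
      } else {
        stop_uvvis(sprintf("unexpected character '%s' in SMILES '%s'", ch, smiles),
                   "uvvisdb_parse_error")
      }
      if (!is.na(prev)) add_bond(prev, a, pending)
      prev <- a; pending <- NA_real_
    }
  }
  if (length(rings) > 0L) stop_uvvis("unmatched ring-closure digit", "uvvisdb_parse_error")

  mol <- structure(list(
    atoms = data.frame(element = element, aromatic = aromatic,
                       charge = charge, hcount = hexp,
                       stringsAsFactors = FALSE),
    bonds = data.frame(from = from, to = to, order = order, aromatic = barom)
  ), class = "uvvis_mol")
  mol$atoms$hcount <- resolve_hcounts(mol)
  mol
}

# total H per atom: explicit bracket count where given, else the organic
# subset implicit rule (smallest allowed valence covering the bond-order sum;
# aromatic atoms consume one extra unit for the delocalized system)
resolve_hcounts <- function(mol) {
  a <- mol$atoms; b <- mol$bonds
  consumed <- numeric(nrow(a))
  if (nrow(b)) {
    for (k in seq_len(nrow(b))) {
      o <- b$order[k]
      consumed[b$from[k]] <- consumed[b$from[k]] + o
      consumed[b$to[k]] <- consumed[b$to[k]] + o
    }
  }
  out <- integer(nrow(a))
  for (i in seq_len(nrow(a))) {
    if (!is.na(a$hcount[i])) { out[i] <- a$hcount[i]; next }
    val <- .VALENCES[[a$element[i]]]
    if (is.null(val)) { out[i] <- 0L; next }
    # aromatic C/N/B/P consume one valence unit for the delocalized system;
    # aromatic O/S/Se contribute a lone pair instead, not a bond
    arom_extra <- a$aromatic[i] && !(a$element[i] %in% c("O", "S", "Se", "Te"))
    need <- consumed[i] + if (arom_extra) 1 else 0
    fit <- val[val >= need]
    out[i] <- if (length(fit)) as.integer(fit[1] - need) else 0L
  }
  out
}

#' Total electron count of a neutral molecule
#'
#' Sum of atomic numbers over all atoms, implicit hydrogens included: the
#' NEL metric used to band compounds by computational cost.
#'
#' @param mol a `uvvis_mol` (or a SMILES string, parsed on the fly).
#' @return integer electron count.
#' @examples
#' electron_count("c1ccccc1")  # benzene: 42
#' @export
electron_count <- function(mol) {
  mol <- as_uvvis_mol(mol)
  if (any(mol$atoms$charge != 0L)) {
    stop_uvvis("electron_count requires a neutral molecule (composition check runs first)",
               "uvvisdb_precondition_error")
  }
  z <- .ATOMIC_NUMBER[mol$atoms$element]
  if (anyNA(z)) {
    stop_uvvis(sprintf("unknown element(s): %s",
                       paste(unique(mol$atoms$element[is.na(z)]), collapse = ", ")),
               "uvvisdb_precondition_error")
  }
  as.integer(sum(z) + sum(mol$atoms$hcount))
}

as_uvvis_mol <- function(x) {
  if (inherits(x, "uvvis_mol")) x else parse_smiles(x)
}

# adjacency list of a molecule
mol_adjacency <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$from[k]; j <- mol$bonds$to[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# connected components; returns integer component id per atom
mol_components <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- mol_adjacency(mol)
  comp <- integer(n); cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] != 0L) next
      comp[v] <- cur
      queue <- c(queue, adj[[v]][comp[adj[[v]]] == 0L])
    }
  }
  comp
}

# which atoms sit on a cycle: endpoints of non-bridge edges.
# brute force (drop edge, test connectivity) -- molecules are small.
ring_atom_mask <- function(mol) {
  n <- nrow(mol$atoms)
  inring <- logical(n)
  b <- mol$bonds
  if (!nrow(b)) return(inring)
  for (k in seq_len(nrow(b))) {
    sub <- b[-k, , drop = FALSE]
    if (connected_between(n, sub, b$from[k], b$to[k])) {
      inring[b$from[k]] <- TRUE
      inring[b$to[k]] <- TRUE
    }
  }
  inring
}

connected_between <- function(n, bonds, a, bt) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds$from[k]; j <- bonds$to[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  seen <- logical(n)
  queue <- a
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    if (seen[v]) next
    seen[v] <- TRUE
    if (v == bt) return(TRUE)
    queue <- c(queue, adj[[v]][!seen[adj[[v]]]])
  }
  seen[bt]
}

#' Write a molecular graph back to SMILES
#'
#' Produces a valid (not necessarily toolkit-canonical) SMILES string; the
#' filter re-canonicalizes through the toolkit after structural edits.
#'
#' @param mol a `uvvis_mol`.
#' @return a SMILES string.
#' @export
write_smiles <- function(mol) {
  n <- nrow(mol$atoms)
  if (n == 0L) return("")
  b <- mol$bonds
  bkey <- function(i, j) paste0(min(i, j), "_", max(i, j))
  bmap <- new.env(parent = emptyenv())
  if (nrow(b)) for (k in seq_len(nrow(b))) assign(bkey(b$from[k], b$to[k]), k, envir = bmap)
  adj <- mol_adjacency(mol)
  molx <- mol
  molx$atoms$hcount <- NA_integer_
  implicit <- resolve_hcounts(molx)

  bond_sym <- function(k) {
    if (b$aromatic[k]) return("")
    switch(as.character(b$order[k]), "1" = "", "2" = "=", "3" = "#", "")
  }
  # single bond between two aromatic atoms must be written explicitly
  bond_sym_ctx <- function(k) {
    s <- bond_sym(k)
    if (s == "" && !b$aromatic[k] &&
        mol$atoms$aromatic[b$from[k]] && mol$atoms$aromatic[b$to[k]]) "-" else s
  }
  atom_tok <- function(i) {
    a <- mol$atoms[i, ]
    plain <- a$element %in% .ORGANIC_SUBSET && a$charge == 0L &&
      a$hcount == implicit[i]
    sym <- if (a$aromatic) tolower(a$element) else a$element
    if (plain) return(sym)
    h <- if (a$hcount == 0L) "" else if (a$hcount == 1L) "H" else paste0("H", a$hcount)
    ch <- if (a$charge == 0L) ""
    else if (a$charge == 1L) "+" else if (a$charge == -1L) "-"
    else sprintf("%+d", a$charge)
    paste0("[", sym, h, ch, "]")
  }

  visited <- logical(n)
  ring_digit <- 0L
  ring_open <- vector("list", n)  # digits closing at each atom, set by descendants

  # DFS spanning tree; back edges become ring closures.  Children are
  # traversed *before* the atom's piece is assembled, so ring-closure digits
  # registered on an ancestor by its descendants are in place when the
  # ancestor's own token is finalized (back edges always point to an atom on
  # the current DFS stack).
  edge_used <- logical(nrow(b))
  dfs <- function(v) {
    visited[v] <<- TRUE
    self_closures <- character()
    kids <- character()
    for (w in adj[[v]]) {
      k <- get(bkey(v, w), envir = bmap)
      if (edge_used[k]) next
      edge_used[k] <<- TRUE
      if (visited[w]) {
        ring_digit <<- ring_digit + 1L
        d <- if (ring_digit < 10L) as.character(ring_digit) else sprintf("%%%02d", ring_digit)
        self_closures <- c(self_closures, paste0(bond_sym_ctx(k), d))
        ring_open[[w]] <<- c(ring_open[[w]], d)
      } else {
        kids <- c(kids, paste0(bond_sym_ctx(k), dfs(w)))
      }
    }
    piece <- paste0(atom_tok(v),
                    paste0(unlist(ring_open[[v]]), collapse = ""),
                    paste0(self_closures, collapse = ""))
    if (length(kids) > 1L) {
      piece <- paste0(piece, paste0("(", kids[-length(kids)], ")", collapse = ""),
                      kids[length(kids)])
    } else if (length(kids) == 1L) {
      piece <- paste0(piece, kids)
    }
    piece
  }

  frags <- character()
  for (s in seq_len(n)) {
    if (!visited[s]) frags <- c(frags, dfs(s))
  }
  paste0(frags, collapse = ".")
}
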