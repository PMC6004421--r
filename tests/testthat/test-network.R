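test_that("bundled networks match the printed node, gene and model counts", {
    nets <- bundledNetworks()
    counts <- vapply(nets, countAlternatives, integer(1L))
    expect_identical(counts[["serine_biosynthesis"]], 1L)
    expect_identical(counts[["pi3k_akt"]], 12L)
    expect_identical(counts[["mapk"]], 192L)
    expect_identical(counts[["neurotrophin"]], 3L)
    expect_identical(counts[["focal_adhesion"]], 1296L)
    nNodes <- vapply(nets, function(n) length(networkNodes(n)),
        integer(1L))
    expect_identical(unname(nNodes[c("serine_biosynthesis", "pi3k_akt",
        "mapk", "neurotrophin", "focal_adhesion")]),
        c(5L, 11L, 11L, 9L, 11L))
    nGenes <- vapply(nets, function(n) length(uniqueGenes(n)),
        integer(1L))
    expect_identical(unname(nGenes[c("serine_biosynthesis", "pi3k_akt",
        "mapk", "neurotrophin", "focal_adhesion")]),
        c(5L, 17L, 20L, 11L, 27L))
})

test_that("the five bundled pathways cover 69 unique genes", {
    expect_length(uniqueGenes(unname(bundledNetworks())), 69L)
    # idempotence: a duplicated network adds nothing
    one <- bundledNetworks("serine_biosynthesis")
    expect_identical(uniqueGenes(list(one, one)), uniqueGenes(one))
    expect_length(uniqueGenes(one), 5L)
})

test_that("network JSON validation names the offending element", {
    tmp <- tempfile(fileext = ".json")
    writeLines('{"name":"bad","nodes":[{"id":"A","members":["g1"]}],
        "edges":[["A","NOPE"]]}', tmp)
    expect_error(loadNetwork(tmp), "NOPE")
    writeLines('{"name":"bad","nodes":[{"id":"A","members":[]}],
        "edges":[]}', tmp)
    expect_error(loadNetwork(tmp), "empty member")
    expect_error(PathwayNetwork("dup",
        nodes = list(A = "g1", A = "g2")), "duplicate node id")
})

test_that("write -> load round-trips network structure", {
    net <- bundledNetworks("focal_adhesion")
    tmp <- tempfile(fileext = ".json")
    writeNetwork(net, tmp)
    net2 <- loadNetwork(tmp)
    expect_identical(networkNodes(net2), networkNodes(net))
    expect_identical(nodeMembers(net2), nodeMembers(net))
    expect_identical(networkEdges(net2), networkEdges(net))
    expect_identical(net2@latent, net@latent)
})

test_that("enumeration is lexicographic, complete and duplicate-free", {
    net <- PathwayNetwork("two",
        nodes = list(A = c("a1", "a2"), B = "b"),
        edges = list(c("A", "B")))
    alts <- enumerateAlternatives(net)
    expect_identical(vapply(alts, function(a) unname(a@assignment["A"]),
        character(1L)), c("a1", "a2"))
    pi3k <- bundledNetworks("pi3k_akt")
    alts <- enumerateAlternatives(pi3k)
    expect_length(alts, 12L)
    keys <- vapply(alts, function(a) paste(a@assignment, collapse = "|"),
        character(1L))
    expect_identical(anyDuplicated(keys), 0L)
    # property: length always equals the member-count product
    for (seed in 1:10) {
        rn <- randomComplexNetwork(seed)
        expect_length(enumerateAlternatives(rn), countAlternatives(rn))
    }
})

test_that("resolved edges are the parent edges relabeled node -> gene", {
    for (seed in 1:5) {
        rn <- randomComplexNetwork(seed)
        for (alt in enumerateAlternatives(rn)) {
            e <- resolvedEdges(alt)
            parent <- networkEdges(rn)
            expect_identical(dim(e), dim(parent))
            expect_identical(unname(e),
                unname(matrix(alt@assignment[parent], ncol = 2L)))
        }
    }
})

test_that("the enumeration cap stops runaway expansion", {
    net <- bundledNetworks("focal_adhesion")
    expect_error(enumerateAlternatives(net, cap = 100L), "cap")
    expect_length(enumerateAlternatives(net, cap = 2000L), 1296L)
})

test_that("models beyond 14 nodes are rejected for SEM fitting", {
    nodes <- as.list(sprintf("g%d", 1:15))
    names(nodes) <- sprintf("N%d", 1:15)
    net <- PathwayNetwork("big", nodes = nodes,
        edges = list(c("N1", "N2")))
    expect_error(semFromNetwork(enumerateAlternatives(net)[[1L]]),
        "14 nodes")
})

test_that("GMT files round-trip as named gene-set lists", {
    tmp <- tempfile(fileext = ".gmt")
    writeLines(c("setA\tfirst set\tg1\tg2\tg3",
        "setB\tsecond set\tg2\tg4"), tmp)
    sets <- readGmt(tmp)
    expect_identical(names(sets), c("setA", "setB"))
    expect_identical(sets$setA, c("g1", "g2", "g3"))
    expect_identical(unname(attr(sets, "description")["setB"]),
        "second set")
    writeLines("broken line", tmp)
    expect_error(readGmt(tmp), "malformed")
})
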