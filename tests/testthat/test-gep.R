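test_that("tail_length follows t = h(n_max - 1) + 1", {
  expect_identical(tail_length(7, 2), 8L)
  expect_identical(tail_length(1, 1), 1L)
  expect_identical(tail_length(10, 2), 11L)
  expect_error(tail_length(0, 2), ">= 1")
})

test_that("Karva decoding is level-order", {
  expect_equal(tree_to_infix(decode_karva(c("+", "d0", "d1"))), "(d0+d1)")
  # root *, children (+, d0); + gets (d1, d2)
  tr <- decode_karva(c("*", "+", "d0", "d1", "d2", "d0", "d0"))
  expect_equal(tree_to_infix(tr), "((d1+d2)*d0)")
  # unary root consumes one child; the rest is ignored
  tr2 <- decode_karva(c("Cos", "d0", "d1", "d4"))
  expect_equal(tree_to_infix(tr2), "Cos(d0)")
  expect_error(gep_chromosome(c("+", "d0", "+"), head = 1),
               "terminals only")
})

test_that("chromosome construction enforces invariants", {
  g <- gep_chromosome(c("+", "Tan", "d0", "d1", "d2", "d0", "d1"),
                      head = 3, n_terminals = 3)
  expect_s3_class(g, "gep_chromosome")
  expect_error(gep_chromosome(c("+", "d0", "d1"), head = 3), "length")
  expect_error(gep_chromosome(c("+", "q9", "d1"), head = 1), "unknown")
})

test_that("evaluate_tree handles basics, guards, and matches the oracle", {
  dat <- data.frame(d0 = 2, d1 = 3)
  expect_equal(evaluate_tree(decode_karva(c("+", "d0", "d1")), dat), 5)
  expect_equal(evaluate_tree(parse_model_expression("Inv(d0)"),
                             data.frame(d0 = 4)), 0.25)
  # guarded division by zero saturates at 1e6
  expect_equal(evaluate_tree(parse_model_expression("d0/d1"),
                             data.frame(d0 = 1, d1 = 0)), 1e6)
  expect_equal(evaluate_tree(parse_model_expression("Inv(d0)"),
                             data.frame(d0 = 0)), 1e6)

  set.seed(12)
  env <- as.data.frame(matrix(runif(50, -3, 3), 10, 5))
  names(env) <- paste0("d", 0:4)
  for (i in 1:50) {
    tr <- random_tree(4)
    expect_equal(evaluate_tree(tr, env),
                 oracle_eval(as_oracle_tree(tr), env), tolerance = 1e-12)
  }
})

test_that("R interpreter and C++ population evaluator agree", {
  set.seed(13)
  X <- matrix(runif(40, -2, 2), 8, 5)
  dat <- as.data.frame(X)
  names(dat) <- paste0("d", 0:4)
  for (i in 1:60) {
    ch <- random_chromosome(head = 6, n_terminals = 5,
                            n_genes = sample(1:3, 1))
    codes <- qsarflow:::chromosome_to_codes(ch)
    glen <- 6L + tail_length(6L)
    cpp <- gep_eval_population(matrix(codes, 1), X,
                               gep_function_set()$arity, 6L, glen,
                               length(ch$genes), 0L)[, 1]
    expect_equal(evaluate_tree(decode_karva(ch), dat), cpp,
                 tolerance = 1e-12)
  }
})

test_that("fitness follows 1000/(1+RMSE) and the correlation variant", {
  y <- c(1, 2, 3)
  expect_equal(gep_fitness(y, y), 1000)
  expect_equal(gep_fitness(y + 1, y), 500)
  set.seed(14)
  p <- rnorm(20); yy <- rnorm(20)
  expect_equal(gep_fitness(p, yy), 1000 / (1 + sqrt(mean((p - yy)^2))),
               tolerance = 1e-12)
  expect_equal(gep_fitness(p, yy, "correlation"), cor(p, yy)^2,
               tolerance = 1e-12)
  expect_error(gep_fitness(p, rep(1, 20), "correlation"), "zero-variance")
})

test_that("elite roulette keeps the best and samples proportionally", {
  expect_identical(select_elite_roulette(5, 1, elitism = 1), 1L)
  set.seed(15)
  sel <- select_elite_roulette(c(3, 1), n_select = 1e5, elitism = 0)
  n1 <- sum(sel == 1L)
  # chi-square against the 3:1 multinomial at the 99% level
  chi <- (n1 - 75000)^2 / 75000 + (1e5 - n1 - 25000)^2 / 25000
  expect_lt(chi, qchisq(0.99, df = 1))
  # elitism contract: index of the best always first
  fit <- c(0.2, 5, 1)
  for (i in 1:20) expect_identical(select_elite_roulette(fit, 3)[1], 2L)
  expect_warning(sel0 <- select_elite_roulette(c(0, 0, 0), 10, elitism = 0),
                 "uniform")
  expect_length(sel0, 10L)
})

test_that("genetic operators preserve invariants and degenerate correctly", {
  set.seed(16)
  ch <- random_chromosome(head = 7, n_terminals = 5, n_genes = 2)
  expect_identical(mutate(ch, 0), ch)
  twins <- recombine_one_point(ch, ch)
  expect_identical(twins[[1]], ch)
  expect_identical(twins[[2]], ch)
  # fuzz all operators (deep fuzz lives in the acceptance suite)
  for (i in 1:500) {
    a <- random_chromosome(head = sample(2:8, 1), n_terminals = 5,
                           n_genes = sample(1:3, 1))
    b <- random_chromosome(head = a$head, n_terminals = 5,
                           n_genes = length(a$genes))
    expect_true(validate_chromosome(mutate(a, 0.2)))
    expect_true(validate_chromosome(recombine_one_point(a, b)[[1]]))
    expect_true(validate_chromosome(recombine_two_point(a, b)[[2]]))
    expect_true(validate_chromosome(recombine_gene(a, b)[[1]]))
    expect_true(validate_chromosome(transpose_is(a)))
    expect_true(validate_chromosome(transpose_ris(a)))
    expect_true(validate_chromosome(transpose_gene(a)))
  }
})

test_that("encode/decode round-trips trees that fit the head", {
  set.seed(17)
  for (i in 1:300) {
    tr <- random_tree(3)
    g <- encode_tree(tr, head = 15)
    expect_equal(tree_to_infix(decode_karva(g)), tree_to_infix(tr))
  }
  # level order of d0+(d1+d2) is (+ d0 + d1 d2): the second + lands at
  # position 3, beyond a head of 2
  expect_error(encode_tree(parse_model_expression("d0+(d1+d2)"), head = 2),
               "head")
  expect_error(encode_tree(
    parse_model_expression("d0+d1+d2+d3+d4+d0+d1+d2+d3"), head = 2),
    "symbols")
})

test_that("evolution is reproducible, monotone, and solves identity", {
  gen <- gen_symbolic("d0", n = 25, seed = 5)
  cfg <- gep_config(population = 100, generations = 30, head = 6,
                    n_genes = 1, seed = 77)
  r1 <- gep_evolve(gen$X, gen$y, cfg)
  r2 <- gep_evolve(gen$X, gen$y, cfg)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$best, r2$best)
  expect_true(all(diff(r1$history) >= 0))
  # identity target: should be solved almost immediately
  cfg2 <- gep_config(population = 200, generations = 50, head = 6,
                     seed = 78, stop_fitness = 1000 * (1 - 1e-9))
  r3 <- gep_evolve(gen$X, gen$y, cfg2)
  expect_gte(summary_metrics(gen$y, r3$predictions, 1)$r2, 0.999)
})

test_that("expression parser follows the documented convention", {
  expect_equal(tree_to_infix(parse_model_expression("d0+d1")), "(d0+d1)")
  # unary binds tighter than *
  expect_equal(tree_to_infix(parse_model_expression("Cosd0*d2")),
               "(Cos(d0)*d2)")
  # left association of /
  expect_equal(tree_to_infix(parse_model_expression("Cos1/d3/d0")),
               "((Cos(1)/d3)/d0)")
  expect_equal(tree_to_infix(parse_model_expression("TanTand0")),
               "Tan(Tan(d0))")
  expect_equal(tree_to_infix(parse_model_expression("(d0+d1)*d2")),
               "((d0+d1)*d2)")
  expect_error(parse_model_expression("d0 $ d1"), "position")
  expect_error(parse_model_expression("d0+"), "parse error")
})

test_that("published symbolic model parses and both interpreters agree", {
  pm <- gep_published_model()
  expect_named(pm$binding, paste0("d", 0:4))
  expect_equal(unname(pm$binding["d2"]), "YZS_YZR")
  set.seed(18)
  env <- as.data.frame(matrix(runif(25, 0.5, 1.5), 5, 5))
  names(env) <- paste0("d", 0:4)
  expect_equal(evaluate_tree(pm$tree, env),
               oracle_eval(as_oracle_tree(pm$tree), env), tolerance = 1e-12)
  ones <- data.frame(d0 = 1, d1 = 1, d2 = 1, d3 = 1, d4 = 1)
  expect_equal(evaluate_tree(pm$tree, ones),
               oracle_eval(as_oracle_tree(pm$tree), ones), tolerance = 1e-12)
})
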