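test_that("binding resolves every node to a same-named function", {
  fx <- make_string_pipeline()
  pr <- lgl_project(fx$source)
  expect_length(pr$bindings, 3L)
  expect_setequal(names(list_states(pr)),
                  c("first_task", "second_task", "third_task"))
})

test_that("a missing node function is a binding error naming the node", {
  fx <- make_string_pipeline()
  fns <- load_node_source <- new.env()
  fns$first_task <- function() "hello"
  fns$third_task <- function(x) paste0(x, "-3")
  expect_error(lgl_project(fns, lgl = fx$lgl), "second_task")
})

test_that("an arity mismatch is a binding error", {
  fns <- list(
    a = function() 1,
    b = function() 2, # should take 1 argument
    c = function(x, y) x + y
  )
  expect_error(lgl_project(fns, lgl = "a -> b; b -> c; a -> c;"),
               "1 incoming edge")
  # functions with ... accept any arity
  fns$b <- function(...) sum(...)
  pr <- lgl_project(fns, lgl = "a -> b; b -> c; a -> c;")
  expect_equal(provide(pr, "c"), 2)
})

test_that("a cyclic pipeline is rejected at bind time", {
  fns <- list(a = function(x) x, b = function(x) x)
  expect_error(lgl_project(fns, lgl = "a -> b; b -> a;"), "cycle")
})

test_that("provide is lazy: unrelated branches never execute", {
  fx <- make_string_pipeline()
  pr <- lgl_project(fx$source)
  expect_equal(provide(pr, "second_task"), "hello-2")
  runs <- node_runs(pr)
  expect_equal(runs[["third_task"]], 0L)
  expect_equal(runs[["first_task"]], 1L)
})

test_that("a repeated provide performs zero executions", {
  fx <- make_string_pipeline()
  pr <- lgl_project(fx$source)
  provide(pr, "second_task")
  before <- node_runs(pr)
  expect_equal(provide(pr, "second_task"), "hello-2")
  expect_identical(node_runs(pr), before)
})

test_that("a cold chain executes every ancestor exactly once, in order", {
  fns <- list(
    s1 = function() "s1",
    s2 = function(x) paste0(x, ">s2"),
    s3 = function(x) paste0(x, ">s3"),
    s4 = function(x) paste0(x, ">s4"),
    s5 = function(x) paste0(x, ">s5")
  )
  pr <- lgl_project(fns, lgl = "s1 -> s2; s2 -> s3; s3 -> s4; s4 -> s5;")
  expect_equal(provide(pr, "s5"), "s1>s2>s3>s4>s5")
  expect_true(all(node_runs(pr) == 1L))
})

test_that("run provides all leaf resources, sharing the common ancestor", {
  fx <- make_string_pipeline()
  pr <- lgl_project(fx$source)
  res <- run_pipeline(pr)
  expect_mapequal(res, list(second_task = "hello-2", third_task = "hello-3"))
  expect_equal(node_runs(pr)[["first_task"]], 1L)
})

test_that("run on a single isolated node equals provide", {
  fns <- list(only = function() 42)
  pr <- lgl_project(fns, lgl = "only;")
  expect_equal(run_pipeline(pr), list(only = 42))
  expect_equal(provide(pr, "only"), 42)
})

test_that("multi-parent nodes receive arguments in incoming-edge creation order", {
  fns <- list(
    left = function() "L",
    right = function() "R",
    join = function(a, b) paste0(a, "|", b)
  )
  pr1 <- lgl_project(fns, lgl = "left -> join; right -> join;")
  expect_equal(provide(pr1, "join"), "L|R")
  pr2 <- lgl_project(fns, lgl = "right -> join; left -> join;")
  expect_equal(provide(pr2, "join"), "R|L")
})

test_that("fan-out sends the identical resource along each edge", {
  fns <- list(
    src = function() list(x = 1:5),
    a = function(v) serialize(v, NULL),
    b = function(v) serialize(v, NULL)
  )
  pr <- lgl_project(fns, lgl = "src -> a, b;")
  res <- run_pipeline(pr)
  expect_identical(res$a, res$b)
})

test_that("node failures propagate the original error after being recorded", {
  fns <- list(
    ok = function() 1,
    boom = function(x) stop("deliberate failure inside boom"),
    after = function(x) x + 1
  )
  pr <- lgl_project(fns, lgl = "ok -> boom; boom -> after;")
  expect_error(provide(pr, "after"), "deliberate failure inside boom")
  st <- list_states(pr)
  expect_equal(st[["boom"]], "unavailable")
  expect_equal(st[["ok"]], "available") # built ancestors are not rolled back
  expect_equal(node_runs(pr)[["after"]], 0L)
})

test_that("detect_code_changes invalidates the edited node and its descendants", {
  fx <- make_string_pipeline()
  pd <- new_project_dir()
  pr <- lgl_project(fx$source, project_dir = pd)
  run_pipeline(pr)

  # leaf edit: only that node
  write_string_pipeline(fx$source, suffixes = c(second_task = "-2x", third_task = "-3"))
  inv <- detect_code_changes(pr)
  expect_equal(inv, "second_task")
  st <- list_states(pr)
  expect_equal(st[["second_task"]], "to-be-built")
  expect_equal(st[["first_task"]], "available")
  expect_equal(provide(pr, "second_task"), "hello-2x")

  # root edit: whole pipeline
  write_string_pipeline(fx$source, greeting = "ciao",
                        suffixes = c(second_task = "-2x", third_task = "-3"))
  inv2 <- detect_code_changes(pr)
  expect_setequal(inv2, c("first_task", "second_task", "third_task"))
  expect_equal(provide(pr, "third_task"), "ciao-3")

  # no modification: empty set
  expect_length(detect_code_changes(pr), 0L)
})

test_that("trust suppresses the invalidation cascade until the next edit", {
  fx <- make_string_pipeline()
  pr <- lgl_project(fx$source, project_dir = new_project_dir())
  run_pipeline(pr)
  write_string_pipeline(fx$source, suffixes = c(second_task = "-2b", third_task = "-3"))
  # refresh bindings by re-creating over the same project dir, then trust
  pr2 <- lgl_project(fx$source, project_dir = pr$project_dir)
  trust(pr2, "second_task")
  expect_length(detect_code_changes(pr2), 0L)
  expect_equal(provide(pr2, "second_task"), "hello-2") # old value kept
  # trusting an unchanged node is a no-op
  trust(pr2, "third_task")
  expect_length(detect_code_changes(pr2), 0L)
  # a further edit re-invalidates
  write_string_pipeline(fx$source, suffixes = c(second_task = "-2c", third_task = "-3"))
  expect_equal(detect_code_changes(pr2), "second_task")
})

test_that("trust without a stored resource is an error", {
  fx <- make_string_pipeline()
  pr <- lgl_project(fx$source)
  expect_error(trust(pr, "second_task"), "no stored resource")
})

test_that("untrust clears the node and all dependents; idempotent", {
  fx <- make_string_pipeline()
  pr <- lgl_project(fx$source, project_dir = new_project_dir())
  run_pipeline(pr)
  untrust(pr, "first_task")
  expect_true(all(list_states(pr) == "to-be-built"))
  pr2 <- lgl_project(fx$source, project_dir = new_project_dir())
  run_pipeline(pr2)
  untrust(pr2, "second_task")
  st <- list_states(pr2)
  expect_equal(st[["second_task"]], "to-be-built")
  expect_equal(st[["first_task"]], "available")
  untrust(pr2, "second_task") # idempotent
  expect_identical(list_states(pr2), st)
})

test_that("clear drops the RAM copy only and provide reloads from disk", {
  fx <- make_string_pipeline()
  pr <- lgl_project(fx$source, project_dir = new_project_dir())
  run_pipeline(pr)
  clear_resource(pr, "second_task")
  expect_equal(list_states(pr)[["second_task"]], "dumped")
  before <- node_runs(pr)
  expect_equal(provide(pr, "second_task"), "hello-2")
  expect_identical(node_runs(pr), before) # zero executions: disk reload
  clear_resource(pr, "second_task")
  clear_resource(pr, "second_task") # no-op on absent RAM copy
  expect_equal(list_states(pr)[["second_task"]], "dumped")
})

test_that("undumpall then clearall leaves everything to-be-built", {
  fx <- make_string_pipeline()
  pr <- lgl_project(fx$source, project_dir = new_project_dir())
  run_pipeline(pr)
  undump_all(pr)
  expect_true(all(list_states(pr) == "available"))
  clear_all(pr)
  expect_true(all(list_states(pr) == "to-be-built"))
})

test_that("dumping controls persistence across sessions", {
  fx <- make_string_pipeline()
  pd1 <- new_project_dir()
  pr <- lgl_project(fx$source, project_dir = pd1, dumping = FALSE)
  run_pipeline(pr)
  expect_true(all(list_states(pr) == "available"))
  pr_again <- lgl_project(fx$source, project_dir = pd1)
  expect_true(all(list_states(pr_again) == "to-be-built"))

  pd2 <- new_project_dir()
  pr2 <- lgl_project(fx$source, project_dir = pd2) # dumping on by default
  run_pipeline(pr2)
  pr2_again <- lgl_project(fx$source, project_dir = pd2)
  expect_true(all(list_states(pr2_again) == "dumped"))
  before <- node_runs(pr2_again)
  expect_equal(provide(pr2_again, "second_task"), "hello-2")
  expect_identical(node_runs(pr2_again), before)

  # toggling twice restores behavior
  set_dumping(pr, TRUE)
  set_dumping(pr, FALSE)
  rebuild(pr, "first_task")
  expect_false(file.exists(file.path(pd1, "resources", "p1.blob")))
})

test_that("getinputs returns parent resources as defensive copies", {
  fx <- make_string_pipeline()
  pr <- lgl_project(fx$source)
  ins <- getinputs(pr, "second_task")
  expect_equal(ins, list("hello"))
  expect_equal(getinputs(pr, "first_task"), list())

  fns <- list(src = function() list(v = 1), use = function(x) x$v)
  pr2 <- lgl_project(fns, lgl = "src -> use;")
  inp <- getinputs(pr2, "use")
  inp[[1]]$v <- 999
  expect_equal(provide(pr2, "use"), 1) # cached resource unchanged
})

test_that("the schedule contains exactly the needed waves", {
  fns <- list(A = function() "a", B = function(x) "b", C = function(x) "c",
              D = function(x, y) "d")
  lgl <- "A -> B, C; B -> D; C -> D;"
  pr <- lgl_project(fns, lgl = lgl)
  expect_equal(protocol_schedule(pr, "D"),
               list("A", c("B", "C"), "D"))
  run_pipeline(pr)
  expect_equal(protocol_schedule(pr, "D"), list())

  fns3 <- list(s1 = function() 1, s2 = function(x) x, s3 = function(x) x)
  pr3 <- lgl_project(fns3, lgl = "s1 -> s2; s2 -> s3;",
                     project_dir = new_project_dir())
  provide(pr3, "s2")
  expect_equal(protocol_schedule(pr3, "s3"), list("s3"))
})

test_that("parallel diamond execution equals sequential execution", {
  fns <- list(A = function() "seed",
              B = function(x) paste0(x, ":B"),
              C = function(x) paste0(x, ":C"),
              D = function(b, c) paste(b, c, sep = "+"))
  lgl <- "A -> B, C; B -> D; C -> D;"
  seq_pr <- lgl_project(fns, lgl = lgl, workers = 1L)
  seq_res <- run_pipeline(seq_pr)
  par_pr <- lgl_project(fns, lgl = lgl, workers = 4L)
  par_res <- run_pipeline(par_pr)
  expect_identical(serialize(seq_res, NULL, version = 2),
                   serialize(par_res, NULL, version = 2))
  expect_true(all(node_runs(par_pr) == 1L))
  # B and C sit in the same wave
  expect_equal(protocol_schedule(lgl_project(fns, lgl = lgl), "D")[[2]],
               c("B", "C"))
})

test_that("F-nodes track produced files by modification timestamp", {
  d <- tempfile("fout-")
  dir.create(d)
  fns <- list(
    make = function() "payload",
    save_file = local({
      dd <- d
      function(x) {
        f <- file.path(dd, "out.txt")
        writeLines(x, f)
        f
      }
    })
  )
  pr <- lgl_project(fns, lgl = "make -> save_file[F];",
                    project_dir = new_project_dir())
  run_pipeline(pr)
  expect_true(check_file_outputs(pr, "save_file")$fresh)

  # touching the file makes it stale, and provide rebuilds it
  Sys.setFileTime(file.path(d, "out.txt"), Sys.time() + 7)
  chk <- check_file_outputs(pr, "save_file")
  expect_false(chk$fresh)
  expect_equal(basename(chk$stale), "out.txt")
  before <- node_runs(pr)[["save_file"]]
  provide(pr, "save_file")
  expect_equal(node_runs(pr)[["save_file"]], before + 1L)
  expect_true(check_file_outputs(pr, "save_file")$fresh)

  # deleting the file also triggers a rebuild
  unlink(file.path(d, "out.txt"))
  expect_false(check_file_outputs(pr, "save_file")$fresh)
  provide(pr, "save_file")
  expect_true(file.exists(file.path(d, "out.txt")))

  expect_error(check_file_outputs(pr, "make"), "F flag")
})

test_that("an F-node whose resource is not file names is a build-time type error", {
  fns <- list(bad = function() 12345)
  pr <- lgl_project(fns, lgl = "bad[F];")
  expect_error(run_pipeline(pr), "must return the name")
})

test_that("unknown and ambiguous labels are lookup errors", {
  fx <- make_string_pipeline()
  pr <- lgl_project(fx$source)
  expect_error(provide(pr, "nope"), "unknown pipeline node")
})

test_that("a protocol reconstructs all states from a prior session without executing", {
  fx <- random_dag(6, 0.5, seed = 11)
  pd <- new_project_dir()
  pr <- lgl_project(fx$source, project_dir = pd)
  run_pipeline(pr)
  states1 <- list_states(pr)
  pr2 <- lgl_project(fx$source, project_dir = pd)
  states2 <- list_states(pr2)
  expect_identical(sub("available", "dumped", states1), states2)
  res <- run_pipeline(pr2)
  expect_true(all(node_runs(pr2) == 0L))
  leaves <- sort(unname(graph_leaves(pr2$graph)))
  expect_identical(res[leaves], naive_execute(fx)[leaves])
})
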