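// Voxel finite-element kernels: load-path connectivity filtering, hex mesh
// extraction from an occupancy grid, stiffness triplets for sparse direct
// solves, and a matrix-free element-by-element Jacobi-PCG for large grids.
//
// All elements are identical axis-aligned cubes, so a single 24x24 element
// stiffness matrix (computed in R) serves the whole mesh. Dof ordering is
// node-major: dof = 3*node + component.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <cstdint>
#include <functional>

using namespace Rcpp;

// local node order must match the element stiffness built in R:
// offsets (0,0,0),(1,0,0),(1,1,0),(0,1,0),(0,0,1),(1,0,1),(1,1,1),(0,1,1)

// [[Rcpp::export]]
List vf_load_path(LogicalVector occ, IntegerVector dims, int axis) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  std::vector<int32_t> label(nvox, -1);
  LogicalVector keep(nvox, FALSE);
  auto lin = [&](int i, int j, int k) -> R_xlen_t {
    return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * k);
  };
  int ncomp = 0;
  R_xlen_t dropped = 0, kept = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < nvox; ++s) {
    if (!occ[s] || label[s] >= 0) continue;
    // flood fill one component (6-connectivity)
    bool lo = false, hi = false;
    std::vector<R_xlen_t> members;
    stack.clear();
    stack.push_back(s);
    label[s] = ncomp;
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      members.push_back(v);
      int i = (int)(v % nx);
      int j = (int)((v / nx) % ny);
      int k = (int)(v / ((R_xlen_t)nx * ny));
      int c[3] = {i, j, k};
      int nmax[3] = {nx, ny, nz};
      if (c[axis] == 0) lo = true;
      if (c[axis] == nmax[axis] - 1) hi = true;
      const int di[6] = {-1, 1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, -1, 1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, -1, 1};
      for (int t = 0; t < 6; ++t) {
        int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        R_xlen_t w = lin(ii, jj, kk);
        if (occ[w] && label[w] < 0) {
          label[w] = ncomp;
          stack.push_back(w);
        }
      }
    }
    if (lo && hi) {
      for (R_xlen_t v : members) keep[v] = TRUE;
      kept += (R_xlen_t)members.size();
    } else {
      dropped += (R_xlen_t)members.size();
    }
    ++ncomp;
  }
  return List::create(_["occ"] = keep,
                      _["n_kept"] = (double)kept,
                      _["n_dropped"] = (double)dropped,
                      _["n_components"] = ncomp);
}

// [[Rcpp::export]]
List vf_mesh(LogicalVector occ, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nnl = (R_xlen_t)(nx + 1) * (ny + 1) * (nz + 1);
  // count elements
  R_xlen_t nel = 0;
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  for (R_xlen_t v = 0; v < nvox; ++v) if (occ[v]) ++nel;
  if (nel == 0) stop("empty grid: no solid voxels");
  std::vector<int32_t> nodemap(nnl, -1);
  auto nlin = [&](int i, int j, int k) -> R_xlen_t {
    return (R_xlen_t)i + (R_xlen_t)(nx + 1) * ((R_xlen_t)j + (R_xlen_t)(ny + 1) * k);
  };
  const int ox[8] = {0, 1, 1, 0, 0, 1, 1, 0};
  const int oy[8] = {0, 0, 1, 1, 0, 0, 1, 1};
  const int oz[8] = {0, 0, 0, 0, 1, 1, 1, 1};
  IntegerMatrix elem(nel, 8);
  // first pass: assign compact node ids in lexicographic element order
  int32_t nextid = 0;
  R_xlen_t e = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t v = (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * k);
        if (!occ[v]) continue;
        for (int a = 0; a < 8; ++a) {
          R_xlen_t nl = nlin(i + ox[a], j + oy[a], k + oz[a]);
          if (nodemap[nl] < 0) nodemap[nl] = nextid++;
          elem(e, a) = nodemap[nl];
        }
        ++e;
      }
  IntegerMatrix coords(nextid, 3);
  for (int k = 0; k <= nz; ++k)
    for (int j = 0; j <= ny; ++j)
      for (int i = 0; i <= nx; ++i) {
        int32_t id = nodemap[nlin(i, j, k)];
        if (id >= 0) { coords(id, 0) = i; coords(id, 1) = j; coords(id, 2) = k; }
      }
  return List::create(_["elem"] = elem, _["coords"] = coords,
                      _["n_nodes"] = (int)nextid);
}

// [[Rcpp::export]]
NumericVector vf_diag(IntegerMatrix elem, NumericMatrix Ke, int n_nodes) {
  NumericVector d(3 * (R_xlen_t)n_nodes, 0.0);
  const R_xlen_t nel = elem.nrow();
  for (R_xlen_t e = 0; e < nel; ++e)
    for (int a = 0; a < 8; ++a) {
      int node = elem(e, a);
      for (int c = 0; c < 3; ++c)
        d[3 * (R_xlen_t)node + c] += Ke(3 * a + c, 3 * a + c);
    }
  return d;
}

// y = K x, element-by-element
static void ebe_matvec(const int* elem, R_xlen_t nel, const double* Ke,
                       const double* x, double* y, R_xlen_t ndof) {
  for (R_xlen_t q = 0; q < ndof; ++q) y[q] = 0.0;
  double xe[24], ye[24];
  for (R_xlen_t e = 0; e < nel; ++e) {
    const int* nd = elem + 8 * e;
    for (int a = 0; a < 8; ++a) {
      const R_xlen_t base = 3 * (R_xlen_t)nd[a];
      xe[3 * a] = x[base]; xe[3 * a + 1] = x[base + 1]; xe[3 * a + 2] = x[base + 2];
    }
    for (int r = 0; r < 24; ++r) {
      const double* row = Ke + 24 * r; // Ke symmetric: column r == row r
      double acc = 0.0;
      for (int c = 0; c < 24; ++c) acc += row[c] * xe[c];
      ye[r] = acc;
    }
    for (int a = 0; a < 8; ++a) {
      const R_xlen_t base = 3 * (R_xlen_t)nd[a];
      y[base] += ye[3 * a]; y[base + 1] += ye[3 * a + 1]; y[base + 2] += ye[3 * a + 2];
    }
  }
}

// [[Rcpp::export]]
NumericVector vf_matvec(IntegerMatrix elem, NumericMatrix Ke, NumericVector x,
                        int n_nodes) {
  const R_xlen_t ndof = 3 * (R_xlen_t)n_nodes;
  if ((R_xlen_t)x.size() != ndof) stop("dof vector has wrong length");
  // copy element table to row-major contiguous ints
  const R_xlen_t nel = elem.nrow();
  std::vector<int> etab(8 * nel);
  for (R_xlen_t e = 0; e < nel; ++e)
    for (int a = 0; a < 8; ++a) etab[8 * e + a] = elem(e, a);
  std::vector<double> ke(24 * 24);
  for (int r = 0; r < 24; ++r)
    for (int c = 0; c < 24; ++c) ke[24 * r + c] = Ke(r, c);
  NumericVector y(ndof);
  ebe_matvec(etab.data(), nel, ke.data(), REAL(x), REAL(y), ndof);
  return y;
}

// Jacobi-preconditioned conjugate gradient with Dirichlet constraints
// handled by masking. fixed/uval give the constrained dofs and their
// imposed values; fext is the external load (zero under displacement
// control). Returns the full displacement vector, K u (for reactions and
// energy), the iteration count, and the final relative residual.
// [[Rcpp::export]]
List vf_pcg(IntegerMatrix elem, NumericMatrix Ke, int n_nodes,
            LogicalVector fixed, NumericVector uval, NumericVector fext,
            double tol, int maxit, Nullable<NumericVector> u0 = R_NilValue) {
  const R_xlen_t ndof = 3 * (R_xlen_t)n_nodes;
  const R_xlen_t nel = elem.nrow();
  std::vector<int> etab(8 * nel);
  for (R_xlen_t e = 0; e < nel; ++e)
    for (int a = 0; a < 8; ++a) etab[8 * e + a] = elem(e, a);
  std::vector<double> ke(24 * 24);
  for (int r = 0; r < 24; ++r)
    for (int c = 0; c < 24; ++c) ke[24 * r + c] = Ke(r, c);

  std::vector<double> u(ndof, 0.0), r(ndof), z(ndof), p(ndof), Ap(ndof),
      dinv(ndof, 0.0);
  // Jacobi diagonal
  for (R_xlen_t e = 0; e < nel; ++e)
    for (int a = 0; a < 8; ++a) {
      R_xlen_t base = 3 * (R_xlen_t)etab[8 * e + a];
      for (int c = 0; c < 3; ++c) dinv[base + c] += ke[24 * (3 * a + c) + (3 * a + c)];
    }
  for (R_xlen_t q = 0; q < ndof; ++q)
    dinv[q] = (dinv[q] > 0.0) ? 1.0 / dinv[q] : 0.0;

  // reference residual norm: constrained values imposed, free dofs zero
  for (R_xlen_t q = 0; q < ndof; ++q) if (fixed[q]) u[q] = uval[q];
  ebe_matvec(etab.data(), nel, ke.data(), u.data(), Ap.data(), ndof);
  double r0 = 0.0;
  for (R_xlen_t q = 0; q < ndof; ++q) {
    r[q] = fixed[q] ? 0.0 : fext[q] - Ap[q];
    r0 += r[q] * r[q];
  }
  r0 = std::sqrt(r0);
  // optional initial guess on the free dofs (e.g. the affine field of the
  // homogeneous problem); convergence stays measured against r0 above
  if (u0.isNotNull()) {
    NumericVector ug(u0);
    if ((R_xlen_t)ug.size() != ndof) stop("initial guess has wrong length");
    for (R_xlen_t q = 0; q < ndof; ++q) if (!fixed[q]) u[q] = ug[q];
    ebe_matvec(etab.data(), nel, ke.data(), u.data(), Ap.data(), ndof);
    for (R_xlen_t q = 0; q < ndof; ++q)
      r[q] = fixed[q] ? 0.0 : fext[q] - Ap[q];
  }
  int it = 0;
  double relres = 0.0;
  double cur = 0.0;
  for (R_xlen_t q = 0; q < ndof; ++q) cur += r[q] * r[q];
  cur = std::sqrt(cur);
  if (r0 > 0.0) relres = cur / r0;
  if (r0 > 0.0 && cur > tol * r0) {
    double rz = 0.0;
    for (R_xlen_t q = 0; q < ndof; ++q) {
      z[q] = fixed[q] ? 0.0 : dinv[q] * r[q];
      p[q] = z[q];
      rz += r[q] * z[q];
    }
    for (it = 1; it <= maxit; ++it) {
      ebe_matvec(etab.data(), nel, ke.data(), p.data(), Ap.data(), ndof);
      double pAp = 0.0;
      for (R_xlen_t q = 0; q < ndof; ++q) {
        if (fixed[q]) Ap[q] = 0.0;
        pAp += p[q] * Ap[q];
      }
      if (pAp <= 0.0) stop("conjugate gradient breakdown: operator not positive definite on the free dofs");
      double alpha = rz / pAp;
      double rn = 0.0;
      for (R_xlen_t q = 0; q < ndof; ++q) {
        u[q] += alpha * p[q];
        r[q] -= alpha * Ap[q];
        rn += r[q] * r[q];
      }
      relres = std::sqrt(rn) / r0;
      if (relres <= tol) break;
      double rz_new = 0.0;
      for (R_xlen_t q = 0; q < ndof; ++q) {
        z[q] = fixed[q] ? 0.0 : dinv[q] * r[q];
        rz_new += r[q] * z[q];
      }
      double beta = rz_new / rz;
      rz = rz_new;
      for (R_xlen_t q = 0; q < ndof; ++q) p[q] = z[q] + beta * p[q];
      if (it % 200 == 0) Rcpp::checkUserInterrupt();
    }
    if (relres > tol)
      stop("conjugate gradient did not converge: relative residual %g after %d iterations", relres, maxit);
  }
  NumericVector uout(ndof), Ku(ndof);
  ebe_matvec(etab.data(), nel, ke.data(), u.data(), Ap.data(), ndof);
  for (R_xlen_t q = 0; q < ndof; ++q) { uout[q] = u[q]; Ku[q] = Ap[q]; }
  return List::create(_["u"] = uout, _["Ku"] = Ku,
                      _["iterations"] = it, _["relres"] = relres);
}

// node-sharing connected components of the mesh (union-find over the 8
// nodes of every element); 1-based component ids per node
// [[Rcpp::export]]
IntegerVector vf_node_components(IntegerMatrix elem, int n_nodes) {
  std::vector<int32_t> parent(n_nodes);
  for (int i = 0; i < n_nodes; ++i) parent[i] = i;
  std::function<int32_t(int32_t)> find = [&](int32_t a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  const R_xlen_t nel = elem.nrow();
  for (R_xlen_t e = 0; e < nel; ++e) {
    int32_t r0 = find(elem(e, 0));
    for (int a = 1; a < 8; ++a) {
      int32_t r = find(elem(e, a));
      if (r != r0) { parent[r] = r0; }
    }
  }
  std::vector<int32_t> remap(n_nodes, -1);
  IntegerVector out(n_nodes);
  int32_t next = 0;
  for (int i = 0; i < n_nodes; ++i) {
    int32_t r = find(i);
    if (remap[r] < 0) remap[r] = next++;
    out[i] = remap[r] + 1;
  }
  return out;
}

// triplets (1-based) for sparse assembly via Matrix::sparseMatrix
// [[Rcpp::export]]
List vf_triplets(IntegerMatrix elem, NumericMatrix Ke) {
  const R_xlen_t nel = elem.nrow();
  const R_xlen_t nt = nel * 24 * 24;
  IntegerVector I(nt), J(nt);
  NumericVector X(nt);
  R_xlen_t t = 0;
  for (R_xlen_t e = 0; e < nel; ++e) {
    int dof[24];
    for (int a = 0; a < 8; ++a)
      for (int c = 0; c < 3; ++c) dof[3 * a + c] = 3 * elem(e, a) + c;
    for (int r = 0; r < 24; ++r)
      for (int c = 0; c < 24; ++c) {
        I[t] = dof[r] + 1; J[t] = dof[c] + 1; X[t] = Ke(r, c);
        ++t;
      }
  }
  return List::create(_["i"] = I, _["j"] = J, _["x"] = X);
}
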