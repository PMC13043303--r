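// Minimal HDF5 reader/writer for the sensor-data container:
//   /data       N_m x N_t float64
//   /dt, /t0    scalar float64
//   /positions  N_m x dim float64
//   meta        JSON string attribute on the root group
// Written against the HDF5 C API (no R HDF5 binding is available); layouts
// are bit-exact round-trips for 64-bit payloads.

#include <RcppArmadillo.h>
#include <hdf5.h>
using namespace arma;
using Rcpp::List;
using Rcpp::Named;

static void write_scalar(hid_t file, const char* name, double value) {
  hid_t sp = H5Screate(H5S_SCALAR);
  hid_t ds = H5Dcreate2(file, name, H5T_IEEE_F64LE, sp, H5P_DEFAULT,
                        H5P_DEFAULT, H5P_DEFAULT);
  H5Dwrite(ds, H5T_NATIVE_DOUBLE, H5S_ALL, H5S_ALL, H5P_DEFAULT, &value);
  H5Dclose(ds); H5Sclose(sp);
}

// write a column-major arma matrix as a row-major (nrow, ncol) dataset
static void write_matrix(hid_t file, const char* name, const mat& x) {
  hsize_t dims[2] = {(hsize_t)x.n_rows, (hsize_t)x.n_cols};
  mat xt = x.t();  // column-major transpose == row-major original
  hid_t sp = H5Screate_simple(2, dims, NULL);
  hid_t ds = H5Dcreate2(file, name, H5T_IEEE_F64LE, sp, H5P_DEFAULT,
                        H5P_DEFAULT, H5P_DEFAULT);
  H5Dwrite(ds, H5T_NATIVE_DOUBLE, H5S_ALL, H5S_ALL, H5P_DEFAULT, xt.memptr());
  H5Dclose(ds); H5Sclose(sp);
}

// [[Rcpp::export(name = ".h5_write_sensor")]]
void h5_write_sensor(std::string path, const arma::mat& d, double dt,
                     double t0, const arma::mat& positions, std::string meta) {
  H5Eset_auto2(H5E_DEFAULT, NULL, NULL);
  hid_t file = H5Fcreate(path.c_str(), H5F_ACC_TRUNC, H5P_DEFAULT, H5P_DEFAULT);
  if (file < 0) Rcpp::stop("cannot create HDF5 file '%s'", path.c_str());
  write_matrix(file, "data", d);
  write_scalar(file, "dt", dt);
  write_scalar(file, "t0", t0);
  if (positions.n_elem) write_matrix(file, "positions", positions);
  // meta as a string attribute on the root group
  hid_t atype = H5Tcopy(H5T_C_S1);
  H5Tset_size(atype, meta.size() + 1);
  hid_t asp = H5Screate(H5S_SCALAR);
  hid_t attr = H5Acreate2(file, "meta", atype, asp, H5P_DEFAULT, H5P_DEFAULT);
  H5Awrite(attr, atype, meta.c_str());
  H5Aclose(attr); H5Sclose(asp); H5Tclose(atype);
  H5Fclose(file);
}

static mat read_matrix(hid_t file, const char* name, const std::string& path) {
  hid_t ds = H5Dopen2(file, name, H5P_DEFAULT);
  if (ds < 0) {
    H5Fclose(file);
    Rcpp::stop("dataset '/%s' missing or unreadable in '%s'", name, path.c_str());
  }
  hid_t sp = H5Dget_space(ds);
  hsize_t dims[2] = {0, 0};
  int rank = H5Sget_simple_extent_ndims(sp);
  if (rank != 2) {
    H5Sclose(sp); H5Dclose(ds); H5Fclose(file);
    Rcpp::stop("dataset '/%s' in '%s' is not 2-D", name, path.c_str());
  }
  H5Sget_simple_extent_dims(sp, dims, NULL);
  mat buf((uword)dims[1], (uword)dims[0]);  // col-major (ncol, nrow) = row-major data
  herr_t st = H5Dread(ds, H5T_NATIVE_DOUBLE, H5S_ALL, H5S_ALL, H5P_DEFAULT,
                      buf.memptr());
  H5Sclose(sp); H5Dclose(ds);
  if (st < 0) {
    H5Fclose(file);
    Rcpp::stop("failed reading dataset '/%s' from '%s' (truncated file?)",
               name, path.c_str());
  }
  return buf.t();
}

static double read_scalar(hid_t file, const char* name, const std::string& path) {
  hid_t ds = H5Dopen2(file, name, H5P_DEFAULT);
  if (ds < 0) {
    H5Fclose(file);
    Rcpp::stop("dataset '/%s' missing in '%s'", name, path.c_str());
  }
  double v = 0;
  herr_t st = H5Dread(ds, H5T_NATIVE_DOUBLE, H5S_ALL, H5S_ALL, H5P_DEFAULT, &v);
  H5Dclose(ds);
  if (st < 0) { H5Fclose(file); Rcpp::stop("failed reading '/%s'", name); }
  return v;
}

// [[Rcpp::export(name = ".h5_read_sensor")]]
List h5_read_sensor(std::string path) {
  H5Eset_auto2(H5E_DEFAULT, NULL, NULL);
  hid_t file = H5Fopen(path.c_str(), H5F_ACC_RDONLY, H5P_DEFAULT);
  if (file < 0) Rcpp::stop("cannot open '%s' as HDF5", path.c_str());
  mat d = read_matrix(file, "data", path);
  double dt = read_scalar(file, "dt", path);
  double t0 = read_scalar(file, "t0", path);
  mat pos;
  if (H5Lexists(file, "positions", H5P_DEFAULT) > 0)
    pos = read_matrix(file, "positions", path);
  std::string meta;
  if (H5Aexists(file, "meta") > 0) {
    hid_t attr = H5Aopen(file, "meta", H5P_DEFAULT);
    hid_t atype = H5Aget_type(attr);
    size_t len = H5Tget_size(atype);
    std::vector<char> buf(len + 1, '\0');
    H5Aread(attr, atype, buf.data());
    meta = std::string(buf.data());
    H5Tclose(atype); H5Aclose(attr);
  }
  H5Fclose(file);
  return List::create(Named("d") = d, Named("dt") = dt, Named("t0") = t0,
                      Named("positions") = pos, Named("meta") = meta);
}
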