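/* Minimal HDF5 read/write for the recording container dialect:
 *   /data : double dataset, dims (channels, time)
 *   attributes on /data: fs (double), t0 (double),
 *                        labels, units (variable-length UTF-8 string arrays)
 */
#include <stdlib.h>
#include <string.h>
#include <hdf5.h>
#include <R.h>
#include <Rinternals.h>

static void write_string_attr(hid_t dset, const char *name, SEXP strings)
{
    R_xlen_t n = XLENGTH(strings);
    hid_t stype = H5Tcopy(H5T_C_S1);
    H5Tset_size(stype, H5T_VARIABLE);
    H5Tset_cset(stype, H5T_CSET_UTF8);
    hsize_t dims[1] = { (hsize_t) n };
    hid_t space = H5Screate_simple(1, dims, NULL);
    hid_t attr = H5Acreate2(dset, name, stype, space, H5P_DEFAULT, H5P_DEFAULT);
    const char **buf = (const char **) R_alloc(n, sizeof(char *));
    for (R_xlen_t i = 0; i < n; i++) buf[i] = CHAR(STRING_ELT(strings, i));
    H5Awrite(attr, stype, buf);
    H5Aclose(attr); H5Sclose(space); H5Tclose(stype);
}

static void write_double_attr(hid_t dset, const char *name, double value)
{
    hid_t space = H5Screate(H5S_SCALAR);
    hid_t attr = H5Acreate2(dset, name, H5T_NATIVE_DOUBLE, space,
                            H5P_DEFAULT, H5P_DEFAULT);
    H5Awrite(attr, H5T_NATIVE_DOUBLE, &value);
    H5Aclose(attr); H5Sclose(space);
}

SEXP c_h5_write_recording(SEXP path, SEXP data, SEXP fs, SEXP labels,
                          SEXP units, SEXP t0)
{
    const char *fname = CHAR(STRING_ELT(path, 0));
    SEXP dim = getAttrib(data, R_DimSymbol);
    int nch = INTEGER(dim)[0], nt = INTEGER(dim)[1];

    hid_t file = H5Fcreate(fname, H5F_ACC_TRUNC, H5P_DEFAULT, H5P_DEFAULT);
    if (file < 0) error("cannot create HDF5 file '%s'", fname);

    /* HDF5 is row-major: store (channels, time) so row i is channel i.
     * R matrices are column-major, so transpose into a scratch buffer. */
    double *buf = (double *) R_alloc((size_t) nch * nt, sizeof(double));
    double *x = REAL(data);
    for (int i = 0; i < nch; i++)
        for (int j = 0; j < nt; j++)
            buf[(size_t) i * nt + j] = x[(size_t) j * nch + i];

    hsize_t dims[2] = { (hsize_t) nch, (hsize_t) nt };
    hid_t space = H5Screate_simple(2, dims, NULL);
    hid_t dset = H5Dcreate2(file, "/data", H5T_NATIVE_DOUBLE, space,
                            H5P_DEFAULT, H5P_DEFAULT, H5P_DEFAULT);
    if (dset < 0) { H5Fclose(file); error("cannot create /data dataset"); }
    H5Dwrite(dset, H5T_NATIVE_DOUBLE, H5S_ALL, H5S_ALL, H5P_DEFAULT, buf);

    write_double_attr(dset, "fs", REAL(fs)[0]);
    write_double_attr(dset, "t0", REAL(t0)[0]);
    write_string_attr(dset, "labels", labels);
    write_string_attr(dset, "units", units);

    H5Dclose(dset); H5Sclose(space); H5Fclose(file);
    return R_NilValue;
}

static SEXP read_string_attr(hid_t dset, const char *name, int expected_n)
{
    if (H5Aexists(dset, name) <= 0) return R_NilValue;
    hid_t attr = H5Aopen(dset, name, H5P_DEFAULT);
    hid_t space = H5Aget_space(attr);
    hsize_t n;
    H5Sget_simple_extent_dims(space, &n, NULL);
    hid_t stype = H5Tcopy(H5T_C_S1);
    H5Tset_size(stype, H5T_VARIABLE);
    H5Tset_cset(stype, H5T_CSET_UTF8);
    char **buf = (char **) R_alloc(n, sizeof(char *));
    memset(buf, 0, n * sizeof(char *));
    if (H5Aread(attr, stype, buf) < 0) {
        H5Tclose(stype); H5Sclose(space); H5Aclose(attr);
        return R_NilValue;
    }
    SEXP out = PROTECT(allocVector(STRSXP, (R_xlen_t) n));
    for (hsize_t i = 0; i < n; i++)
        SET_STRING_ELT(out, (R_xlen_t) i,
                       mkCharCE(buf[i] ? buf[i] : "", CE_UTF8));
    H5Dvlen_reclaim(stype, space, H5P_DEFAULT, buf);
    H5Tclose(stype); H5Sclose(space); H5Aclose(attr);
    UNPROTECT(1);
    (void) expected_n;
    return out;
}

static double read_double_attr(hid_t dset, const char *name, double fallback,
                               int *found)
{
    *found = 0;
    if (H5Aexists(dset, name) <= 0) return fallback;
    hid_t attr = H5Aopen(dset, name, H5P_DEFAULT);
    double v = fallback;
    if (H5Aread(attr, H5T_NATIVE_DOUBLE, &v) >= 0) *found = 1;
    H5Aclose(attr);
    return v;
}

SEXP c_h5_read_recording(SEXP path)
{
    const char *fname = CHAR(STRING_ELT(path, 0));
    hid_t file = H5Fopen(fname, H5F_ACC_RDONLY, H5P_DEFAULT);
    if (file < 0) error("cannot open HDF5 file '%s'", fname);
    hid_t dset = H5Dopen2(file, "/data", H5P_DEFAULT);
    if (dset < 0) { H5Fclose(file); error("malformed header: no /data dataset"); }
    hid_t space = H5Dget_space(dset);
    int rank = H5Sget_simple_extent_ndims(space);
    if (rank != 2) {
        H5Sclose(space); H5Dclose(dset); H5Fclose(file);
        error("/data must be a 2-D dataset (channels x time)");
    }
    hsize_t dims[2];
    H5Sget_simple_extent_dims(space, dims, NULL);
    int nch = (int) dims[0], nt = (int) dims[1];

    double *buf = (double *) R_alloc((size_t) nch * nt, sizeof(double));
    H5Dread(dset, H5T_NATIVE_DOUBLE, H5S_ALL, H5S_ALL, H5P_DEFAULT, buf);

    SEXP data = PROTECT(allocMatrix(REALSXP, nch, nt));
    double *x = REAL(data);
    for (int i = 0; i < nch; i++)
        for (int j = 0; j < nt; j++)
            x[(size_t) j * nch + i] = buf[(size_t) i * nt + j];

    int has_fs, has_t0;
    double fs = read_double_attr(dset, "fs", -1.0, &has_fs);
    double t0 = read_double_attr(dset, "t0", 0.0, &has_t0);
    if (!has_fs) {
        H5Sclose(space); H5Dclose(dset); H5Fclose(file);
        UNPROTECT(1);
        error("malformed header: missing fs attribute");
    }
    SEXP labels = PROTECT(read_string_attr(dset, "labels", nch));
    SEXP units = PROTECT(read_string_attr(dset, "units", nch));

    H5Sclose(space); H5Dclose(dset); H5Fclose(file);

    const char *names[] = { "data", "fs", "labels", "units", "t0", "" };
    SEXP out = PROTECT(mkNamed(VECSXP, names));
    SET_VECTOR_ELT(out, 0, data);
    SET_VECTOR_ELT(out, 1, ScalarReal(fs));
    SET_VECTOR_ELT(out, 2, labels);
    SET_VECTOR_ELT(out, 3, units);
    SET_VECTOR_ELT(out, 4, ScalarReal(t0));
    UNPROTECT(4);
    return out;
}
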