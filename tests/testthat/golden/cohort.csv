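patient_id,included,reason,diagnosis_date
P00001,TRUE,ok,2006-10-10
P00002,TRUE,ok,2014-09-15
P00003,TRUE,ok,2003-03-23
P00004,TRUE,ok,2016-09-11
P00005,TRUE,ok,2010-08-26
P00006,TRUE,ok,2007-09-22
P00007,TRUE,ok,2012-07-25
P00008,TRUE,ok,2012-11-30
P00009,TRUE,ok,2004-02-20
P00010,TRUE,ok,2013-05-04
P00011,TRUE,ok,2014-12-07
P00012,TRUE,ok,2006-02-19
P00013,TRUE,ok,2006-12-10
P00014,TRUE,ok,2009-10-11
P00015,TRUE,ok,2016-08-05
P00016,TRUE,ok,2013-11-08
P00017,TRUE,ok,2013-12-27
P00018,TRUE,ok,2008-04-10
P00019,TRUE,ok,2013-01-10
P00020,TRUE,ok,2013-05-30
P00021,FALSE,age_at_dx_lt_35,NA
P00022,TRUE,ok,2007-04-25
P00023,TRUE,ok,2015-12-16
P00024,FALSE,pcos_code,NA
P00025,TRUE,ok,1998-09-25
P00026,TRUE,ok,2007-07-09
P00027,FALSE,age_at_dx_lt_35,NA
P00028,TRUE,ok,2012-01-30
P00029,TRUE,ok,2005-09-18
P00030,TRUE,ok,2009-09-05
P00031,TRUE,ok,2013-01-25
P00032,TRUE,ok,2013-07-03
P00033,TRUE,ok,2010-11-03
P00034,TRUE,ok,2009-02-01
P00035,TRUE,ok,2002-08-24
P00036,FALSE,pcos_code,NA
P00037,TRUE,ok,2009-12-28
P00038,TRUE,ok,2010-11-05
P00039,TRUE,ok,2000-07-23
P00040,TRUE,ok,1999-10-10
P00041,TRUE,ok,2002-05-30
P00042,TRUE,ok,2009-08-29
P00043,FALSE,age_at_dx_lt_35,NA
P00044,TRUE,ok,2013-12-03
P00045,TRUE,ok,2012-10-31
P00046,TRUE,ok,2004-02-04
P00047,TRUE,ok,2008-02-18
P00048,TRUE,ok,2014-06-30
P00049,TRUE,ok,1999-07-24
P00050,TRUE,ok,2016-04-02
P00051,TRUE,ok,2003-12-27
P00052,TRUE,ok,2011-05-01
P00053,TRUE,ok,2006-10-28
P00054,TRUE,ok,2001-11-06
P00055,TRUE,ok,2000-02-23
P00056,TRUE,ok,2013-11-11
P00057,FALSE,insulin_within_12m,NA
P00058,TRUE,ok,1998-02-05
P00059,TRUE,ok,1999-01-15
P00060,TRUE,ok,2014-02-09
P00061,TRUE,ok,2009-01-12
P00062,FALSE,insulin_within_12m,NA
P00063,TRUE,ok,2003-04-14
P00064,TRUE,ok,2009-09-10
P00065,TRUE,ok,2005-03-01
P00066,FALSE,no_diabetes_evidence,NA
P00067,TRUE,ok,2004-08-10
P00068,TRUE,ok,2004-09-23
P00069,TRUE,ok,2010-03-23
P00070,TRUE,ok,2012-12-30
P00071,TRUE,ok,2000-09-19
P00072,TRUE,ok,2014-05-05
P00073,TRUE,ok,2003-09-20
P00074,TRUE,ok,2016-11-20
P00075,TRUE,ok,2011-09-22
P00076,TRUE,ok,2011-11-27
P00077,TRUE,ok,2007-12-04
P00078,TRUE,ok,2011-11-06
P00079,TRUE,ok,2008-07-02
P00080,TRUE,ok,2013-07-31
P00081,FALSE,age_at_dx_lt_35,NA
P00082,TRUE,ok,2014-12-27
P00083,TRUE,ok,2010-03-14
P00084,TRUE,ok,2000-08-06
P00085,TRUE,ok,2012-02-09
P00086,TRUE,ok,2010-01-22
P00087,TRUE,ok,2004-09-30
P00088,TRUE,ok,2014-06-01
P00089,TRUE,ok,2014-05-11
P00090,TRUE,ok,2000-10-08
P00091,TRUE,ok,2005-03-12
P00092,TRUE,ok,2004-08-10
P00093,TRUE,ok,1999-08-27
P00094,FALSE,age_at_dx_lt_35,NA
P00095,FALSE,insulin_within_12m,NA
P00096,TRUE,ok,2005-11-22
P00097,TRUE,ok,2009-03-23
P00098,TRUE,ok,2008-11-24
P00099,TRUE,ok,2012-06-18
P00100,TRUE,ok,2010-11-18
P00101,TRUE,ok,2014-11-12
P00102,TRUE,ok,2013-08-14
P00103,TRUE,ok,2008-11-03
P00104,TRUE,ok,2006-11-15
P00105,TRUE,ok,2002-02-25
P00106,TRUE,ok,2013-08-28
P00107,TRUE,ok,2015-01-25
P00108,TRUE,ok,2014-08-28
P00109,TRUE,ok,2015-07-17
P00110,TRUE,ok,2010-10-08
P00111,TRUE,ok,2005-05-16
P00112,TRUE,ok,2010-07-02
P00113,TRUE,ok,2011-04-15
P00114,TRUE,ok,2012-04-09
P00115,TRUE,ok,2000-05-21
P00116,TRUE,ok,2003-03-19
P00117,TRUE,ok,2010-09-22
P00118,FALSE,insulin_within_12m,NA
P00119,TRUE,ok,2010-01-09
P00120,FALSE,insulin_within_12m,NA
P00121,TRUE,ok,2008-11-18
P00122,TRUE,ok,2001-05-14
P00123,TRUE,ok,2002-11-20
P00124,TRUE,ok,2004-07-16
P00125,TRUE,ok,2003-07-18
P00126,TRUE,ok,2015-04-12
P00127,FALSE,age_at_dx_lt_35,NA
P00128,TRUE,ok,1998-04-21
P00129,FALSE,no_diabetes_evidence,NA
P00130,TRUE,ok,2007-12-03
P00131,TRUE,ok,2016-04-22
P00132,FALSE,pcos_code,NA
P00133,FALSE,pcos_code,NA
P00134,TRUE,ok,2014-06-15
P00135,TRUE,ok,2001-04-23
P00136,TRUE,ok,2012-08-24
P00137,TRUE,ok,2004-11-01
P00138,TRUE,ok,2003-12-24
P00139,TRUE,ok,2002-05-24
P00140,FALSE,age_at_dx_lt_35,NA
P00141,TRUE,ok,2011-10-15
P00142,TRUE,ok,1998-12-20
P00143,TRUE,ok,2000-10-25
P00144,TRUE,ok,2006-11-21
P00145,TRUE,ok,2001-02-24
P00146,TRUE,ok,2008-04-10
P00147,TRUE,ok,2001-05-17
P00148,TRUE,ok,1999-06-27
P00149,TRUE,ok,2015-02-08
P00150,TRUE,ok,2016-10-26
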