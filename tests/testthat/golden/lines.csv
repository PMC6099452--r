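patient_id,class,line,start_date
P00001,metformin,1,2006-10-10
P00002,metformin,1,2014-09-15
P00002,DPP4,2,2014-12-12
P00003,metformin,1,2003-03-23
P00003,TZD,2,2008-05-07
P00004,metformin,1,2016-09-11
P00005,metformin,1,2010-08-26
P00006,metformin,1,2007-09-22
P00006,sulphonylurea,2,2007-10-11
P00006,DPP4,3,2010-04-30
P00006,GLP1,4,2015-10-22
P00007,metformin,1,2012-07-25
P00007,DPP4,2,2015-02-16
P00008,metformin,1,2012-11-30
P00009,metformin,1,2004-02-20
P00010,metformin,1,2013-05-04
P00010,sulphonylurea,2,2015-03-17
P00011,metformin,1,2014-12-07
P00011,sulphonylurea,2,2015-09-29
P00012,sulphonylurea,1,2006-02-19
P00012,metformin,2,2011-03-01
P00013,metformin,1,2006-12-10
P00014,metformin,1,2009-10-11
P00015,metformin,1,2016-08-05
P00016,metformin,1,2013-11-08
P00016,DPP4,2,2014-02-26
P00016,TZD,3,2014-04-14
P00017,sulphonylurea,1,2013-12-27
P00017,DPP4,2,2016-12-26
P00018,other,1,2008-04-10
P00018,sulphonylurea,2,2009-10-04
P00019,metformin,1,2013-01-10
P00019,DPP4,2,2015-02-08
P00020,metformin,1,2013-05-30
P00020,SGLT2,2,2013-12-11
P00022,metformin,1,2007-04-25
P00023,metformin,1,2015-12-16
P00025,metformin,1,1998-09-25
P00025,other,2,1999-09-19
P00025,TZD,3,2005-08-16
P00026,metformin,1,2007-07-09
P00026,sulphonylurea,2,2008-01-18
P00026,DPP4,3,2008-03-06
P00026,GLP1,4,2010-08-02
P00028,metformin,1,2012-01-30
P00028,sulphonylurea,2,2014-12-18
P00029,sulphonylurea,1,2005-09-18
P00029,other,2,2008-04-01
P00029,metformin,3,2012-05-16
P00029,TZD,4,2013-03-06
P00030,metformin,1,2009-09-05
P00030,DPP4,2,2010-04-05
P00031,metformin,1,2013-01-25
P00032,metformin,1,2013-07-03
P00032,sulphonylurea,2,2013-08-20
P00032,DPP4,3,2014-01-12
P00033,metformin,1,2010-11-03
P00034,metformin,1,2009-02-01
P00034,sulphonylurea,2,2010-09-23
P00035,sulphonylurea,1,2002-08-24
P00035,metformin,2,2003-12-31
P00035,TZD,3,2006-03-16
P00035,other,4,2006-10-14
P00037,metformin,1,2009-12-28
P00038,metformin,1,2010-11-05
P00038,sulphonylurea,2,2013-05-31
P00039,metformin,1,2000-07-23
P00040,metformin,1,1999-10-10
P00040,sulphonylurea,2,2008-08-25
P00040,TZD,3,2014-09-06
P00040,other,4,2015-06-15
P00041,metformin,1,2002-05-30
P00042,metformin,1,2009-08-29
P00044,metformin,1,2013-12-03
P00045,sulphonylurea,1,2012-10-31
P00045,DPP4,2,2013-08-27
P00046,metformin,1,2004-02-04
P00047,metformin,1,2008-02-18
P00047,TZD,2,2011-05-26
P00048,sulphonylurea,1,2014-06-30
P00049,metformin,1,1999-07-24
P00050,metformin,1,2016-04-02
P00051,sulphonylurea,1,2003-12-27
P00051,metformin,2,2004-08-01
P00052,metformin,1,2011-05-01
P00052,TZD,2,2012-12-28
P00053,metformin,1,2006-10-28
P00054,sulphonylurea,1,2001-11-06
P00055,sulphonylurea,1,2000-02-23
P00055,TZD,2,2001-02-05
P00055,metformin,3,2004-04-04
P00056,sulphonylurea,1,2013-11-11
P00058,sulphonylurea,1,1998-02-05
P00058,metformin,2,1998-08-31
P00058,TZD,3,1999-10-09
P00059,metformin,1,1999-01-15
P00060,metformin,1,2014-02-09
P00060,TZD,2,2014-03-26
P00061,metformin,1,2009-01-12
P00061,TZD,2,2011-04-08
P00063,sulphonylurea,1,2003-04-14
P00064,sulphonylurea,1,2009-09-10
P00064,TZD,2,2010-10-20
P00065,metformin,1,2005-03-01
P00067,sulphonylurea,1,2004-08-10
P00067,metformin,2,2007-08-03
P00068,other,1,2004-09-23
P00069,metformin,1,2010-03-23
P00069,sulphonylurea,2,2011-02-09
P00069,TZD,3,2014-06-14
P00070,metformin,1,2012-12-30
P00070,sulphonylurea,2,2014-01-20
P00071,metformin,1,2000-09-19
P00071,TZD,2,2006-06-07
P00072,metformin,1,2014-05-05
P00072,sulphonylurea,2,2015-05-02
P00073,metformin,1,2003-09-20
P00074,sulphonylurea,1,2016-11-20
P00075,metformin,1,2011-09-22
P00076,metformin,1,2011-11-27
P00076,sulphonylurea,2,2012-10-24
P00077,sulphonylurea,1,2007-12-04
P00077,TZD,2,2009-06-02
P00078,metformin,1,2011-11-06
P00078,sulphonylurea,2,2015-01-09
P00078,TZD,3,2015-04-27
P00079,metformin,1,2008-07-02
P00080,metformin,1,2013-07-31
P00082,other,1,2014-12-27
P00083,metformin,1,2010-03-14
P00083,sulphonylurea,2,2011-04-25
P00083,DPP4,3,2012-05-30
P00083,other,4,2012-11-07
P00084,sulphonylurea,1,2000-08-06
P00084,TZD,2,2001-01-10
P00085,metformin,1,2012-02-09
P00086,metformin,1,2010-01-22
P00086,DPP4,2,2013-06-25
P00087,sulphonylurea,1,2004-09-30
P00087,other,2,2010-07-30
P00088,metformin,1,2014-06-01
P00088,SGLT2,2,2015-07-28
P00089,metformin,1,2014-05-11
P00090,sulphonylurea,1,2000-10-08
P00090,metformin,2,2005-11-05
P00091,sulphonylurea,1,2005-03-12
P00092,sulphonylurea,1,2004-08-10
P00092,TZD,2,2005-03-23
P00093,metformin,1,1999-08-27
P00093,TZD,2,2004-12-30
P00096,sulphonylurea,1,2005-11-22
P00097,metformin,1,2009-03-23
P00097,sulphonylurea,2,2011-01-05
P00098,metformin,1,2008-11-24
P00098,DPP4,2,2009-01-30
P00099,metformin,1,2012-06-18
P00099,TZD,2,2016-03-16
P00100,metformin,1,2010-11-18
P00100,DPP4,2,2013-02-28
P00101,metformin,1,2014-11-12
P00102,metformin,1,2013-08-14
P00103,metformin,1,2008-11-03
P00104,sulphonylurea,1,2006-11-15
P00104,TZD,2,2008-02-16
P00104,metformin,3,2014-08-13
P00105,metformin,1,2002-02-25
P00105,other,2,2003-10-01
P00106,metformin,1,2013-08-28
P00107,metformin,1,2015-01-25
P00107,SGLT2,2,2016-07-31
P00107,GLP1,3,2016-10-16
P00108,metformin,1,2014-08-28
P00108,DPP4,2,2015-10-01
P00109,metformin,1,2015-07-17
P00110,metformin,1,2010-10-08
P00110,sulphonylurea,2,2011-05-02
P00110,DPP4,3,2013-02-23
P00111,metformin,1,2005-05-16
P00112,metformin,1,2010-07-02
P00113,metformin,1,2011-04-15
P00113,GLP1,2,2013-04-22
P00113,DPP4,3,2015-10-31
P00114,other,1,2012-04-09
P00114,DPP4,2,2012-06-19
P00115,sulphonylurea,1,2000-05-21
P00115,TZD,2,2004-05-22
P00115,other,3,2005-04-08
P00115,metformin,4,2007-06-29
P00116,metformin,1,2003-03-19
P00116,other,2,2008-11-10
P00117,metformin,1,2010-09-22
P00117,sulphonylurea,2,2015-01-27
P00117,GLP1,3,2015-11-13
P00119,metformin,1,2010-01-09
P00121,metformin,1,2008-11-18
P00121,TZD,2,2009-07-01
P00122,sulphonylurea,1,2001-05-14
P00122,metformin,2,2009-06-05
P00122,TZD,3,2011-04-09
P00123,sulphonylurea,1,2002-11-20
P00123,other,2,2009-08-03
P00124,metformin,1,2004-07-16
P00124,sulphonylurea,2,2008-07-16
P00124,TZD,3,2009-12-20
P00125,sulphonylurea,1,2003-07-18
P00125,other,2,2005-08-29
P00125,TZD,3,2006-05-26
P00126,sulphonylurea,1,2015-04-12
P00128,metformin,1,1998-04-21
P00128,sulphonylurea,2,2001-04-05
P00130,metformin,1,2007-12-03
P00130,sulphonylurea,2,2014-08-22
P00131,sulphonylurea,1,2016-04-22
P00134,metformin,1,2014-06-15
P00135,metformin,1,2001-04-23
P00135,TZD,2,2001-09-27
P00136,metformin,1,2012-08-24
P00137,metformin,1,2004-11-01
P00137,sulphonylurea,2,2009-08-07
P00137,TZD,3,2011-10-17
P00137,other,4,2012-01-23
P00138,metformin,1,2003-12-24
P00139,sulphonylurea,1,2002-05-24
P00139,metformin,2,2004-06-28
P00141,metformin,1,2011-10-15
P00141,GLP1,2,2013-09-04
P00141,TZD,3,2015-07-22
P00142,metformin,1,1998-12-20
P00142,sulphonylurea,2,1999-10-13
P00142,TZD,3,2007-07-10
P00143,sulphonylurea,1,2000-10-25
P00143,TZD,2,2012-09-01
P00143,other,3,2016-09-22
P00144,sulphonylurea,1,2006-11-21
P00145,metformin,1,2001-02-24
P00145,TZD,2,2005-06-06
P00145,other,3,2005-12-26
P00146,metformin,1,2008-04-10
P00146,DPP4,2,2014-01-04
P00146,sulphonylurea,3,2016-05-06
P00147,sulphonylurea,1,2001-05-17
P00148,metformin,1,1999-06-27
P00148,sulphonylurea,2,1999-09-25
P00148,TZD,3,2005-05-16
P00148,other,4,2010-08-09
P00149,metformin,1,2015-02-08
P00150,metformin,1,2016-10-26
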