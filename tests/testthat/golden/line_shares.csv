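calendar_year,line,class,n,percent
1998,1,metformin,3,75
1998,1,sulphonylurea,1,25
1998,2,metformin,1,100
1999,1,metformin,5,100
1999,2,other,1,33.33333333333333
1999,2,sulphonylurea,2,66.66666666666666
1999,3,TZD,1,100
2000,1,metformin,2,28.57142857142857
2000,1,sulphonylurea,5,71.42857142857143
2001,1,metformin,2,40
2001,1,sulphonylurea,3,60
2001,2,TZD,3,75
2001,2,sulphonylurea,1,25
2002,1,metformin,2,40
2002,1,sulphonylurea,3,60
2003,1,metformin,4,57.14285714285714
2003,1,sulphonylurea,3,42.857142857142854
2003,2,metformin,1,50
2003,2,other,1,50
2004,1,metformin,4,50
2004,1,other,1,12.5
2004,1,sulphonylurea,3,37.5
2004,2,TZD,2,50
2004,2,metformin,2,50
2004,3,metformin,1,100
2005,1,metformin,2,40
2005,1,sulphonylurea,3,60
2005,2,TZD,2,50
2005,2,metformin,1,25
2005,2,other,1,25
2005,3,TZD,2,50
2005,3,other,2,50
2006,1,metformin,3,50
2006,1,sulphonylurea,3,50
2006,2,TZD,1,100
2006,3,TZD,2,100
2006,4,other,1,100
2007,1,metformin,4,80
2007,1,sulphonylurea,1,20
2007,2,metformin,1,50
2007,2,sulphonylurea,1,50
2007,3,TZD,1,100
2007,4,metformin,1,100
2008,1,metformin,6,85.71428571428571
2008,1,other,1,14.285714285714285
2008,2,TZD,2,28.57142857142857
2008,2,other,2,28.57142857142857
2008,2,sulphonylurea,3,42.857142857142854
2008,3,DPP4,1,100
2009,1,metformin,7,87.5
2009,1,sulphonylurea,1,12.5
2009,2,DPP4,1,14.285714285714285
2009,2,TZD,2,28.57142857142857
2009,2,metformin,1,14.285714285714285
2009,2,other,1,14.285714285714285
2009,2,sulphonylurea,2,28.57142857142857
2009,3,TZD,1,100
2010,1,metformin,11,100
2010,2,DPP4,1,25
2010,2,TZD,1,25
2010,2,other,1,25
2010,2,sulphonylurea,1,25
2010,3,DPP4,1,100
2010,4,GLP1,1,50
2010,4,other,1,50
2011,1,metformin,6,100
2011,2,TZD,2,28.57142857142857
2011,2,metformin,1,14.285714285714285
2011,2,sulphonylurea,4,57.14285714285714
2011,3,TZD,2,100
2012,1,metformin,7,77.77777777777779
2012,1,other,1,11.11111111111111
2012,1,sulphonylurea,1,11.11111111111111
2012,2,DPP4,1,25
2012,2,TZD,2,50
2012,2,sulphonylurea,1,25
2012,3,DPP4,1,50
2012,3,metformin,1,50
2012,4,other,2,100
2013,1,metformin,10,83.33333333333334
2013,1,sulphonylurea,2,16.666666666666664
2013,2,DPP4,3,37.5
2013,2,GLP1,2,25
2013,2,SGLT2,1,12.5
2013,2,sulphonylurea,2,25
2013,3,DPP4,1,100
2013,4,TZD,1,100
2014,1,metformin,9,81.81818181818183
2014,1,other,1,9.090909090909092
2014,1,sulphonylurea,1,9.090909090909092
2014,2,DPP4,3,42.857142857142854
2014,2,TZD,1,14.285714285714285
2014,2,sulphonylurea,3,42.857142857142854
2014,3,DPP4,1,20
2014,3,TZD,3,60
2014,3,metformin,1,20
2015,1,metformin,4,80
2015,1,sulphonylurea,1,20
2015,2,DPP4,3,33.33333333333333
2015,2,SGLT2,1,11.11111111111111
2015,2,sulphonylurea,5,55.55555555555556
2015,3,DPP4,1,25
2015,3,GLP1,1,25
2015,3,TZD,2,50
2015,4,GLP1,1,50
2015,4,other,1,50
2016,1,metformin,4,66.66666666666666
2016,1,sulphonylurea,2,33.33333333333333
2016,2,DPP4,1,33.33333333333333
2016,2,SGLT2,1,33.33333333333333
2016,2,TZD,1,33.33333333333333
2016,3,GLP1,1,33.33333333333333
2016,3,other,1,33.33333333333333
2016,3,sulphonylurea,1,33.33333333333333
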