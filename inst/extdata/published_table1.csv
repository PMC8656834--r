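row,period,median,q1,q3
total,2007-2009,216.3,176.0,259.5
total,2010-2012,239.5,192.9,289.4
total,2013-2015,236.2,184.5,297.3
total,2016-2018,231.6,188.4,286.1
males,2007-2009,288.6,230.1,337.6
males,2010-2012,316.4,253.1,376.7
males,2013-2015,318.9,253.7,393.2
males,2016-2018,331.1,267.5,396.9
males:35-49,2007-2009,96.5,76.7,113.9
males:35-49,2010-2012,118.8,95.4,142.6
males:35-49,2013-2015,137.0,103.7,170.9
males:35-49,2016-2018,148.8,108.6,183.4
males:50-64,2007-2009,279.8,215.2,342.8
males:50-64,2010-2012,317.5,258.3,378.2
males:50-64,2013-2015,336.1,264.8,416.7
males:50-64,2016-2018,372.6,297.6,447.6
males:65-79,2007-2009,686.2,577.7,855.5
males:65-79,2010-2012,729.6,577.7,911.4
males:65-79,2013-2015,669.3,541.5,894.8
males:65-79,2016-2018,645.2,506.0,831.5
males:80+,2007-2009,1282.0,976.1,1852.0
males:80+,2010-2012,1378.0,1021.0,1832.0
males:80+,2013-2015,1262.0,958.8,1733.0
males:80+,2016-2018,1301.0,970.0,1718.0
females,2007-2009,145.9,108.5,186.1
females,2010-2012,162.8,116.6,206.6
females,2013-2015,148.2,106.5,199.4
females,2016-2018,134.1,98.3,174.3
females:35-49,2007-2009,12.2,8.2,15.7
females:35-49,2010-2012,12.3,7.5,16.3
females:35-49,2013-2015,12.6,8.0,18.4
females:35-49,2016-2018,12.3,7.2,16.0
females:50-64,2007-2009,85.3,37.4,134.4
females:50-64,2010-2012,100.3,63.6,124.5
females:50-64,2013-2015,87.2,54.4,116.8
females:50-64,2016-2018,83.1,57.3,105.8
females:65-79,2007-2009,525.5,393.0,639.3
females:65-79,2010-2012,562.9,421.2,695.6
females:65-79,2013-2015,500.6,370.7,657.5
females:65-79,2016-2018,445.9,315.8,574.5
females:80+,2007-2009,1220.0,917.2,1670.0
females:80+,2010-2012,1372.0,940.0,1974.0
females:80+,2013-2015,1317.0,937.9,1883.0
females:80+,2016-2018,1192.0,881.4,1687.0
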