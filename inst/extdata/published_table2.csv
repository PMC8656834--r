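row,period,p10,p90,gap,ratio
total,2007-2009,146.1,319.9,173.8,2.2
total,2010-2012,147.5,352.1,204.6,2.4
total,2013-2015,147.5,355.5,208.0,2.4
total,2016-2018,149.8,337.9,188.1,2.3
males,2007-2009,192.7,403.2,210.5,2.1
males,2010-2012,205.1,446.1,241.0,2.2
males,2013-2015,211.8,470.3,258.5,2.2
males,2016-2018,215.3,486.5,271.2,2.3
males:35-49,2007-2009,63.2,135.8,72.6,2.1
males:35-49,2010-2012,77.9,159.3,81.4,2.0
males:35-49,2013-2015,82.6,203.1,120.5,2.5
males:35-49,2016-2018,79.2,221.4,142.2,2.8
males:50-64,2007-2009,180.3,408.6,228.3,2.3
males:50-64,2010-2012,203.5,433.1,229.6,2.1
males:50-64,2013-2015,202.8,482.6,279.8,2.4
males:50-64,2016-2018,241.7,535.9,294.2,2.2
males:65-79,2007-2009,472.4,1053.0,580.6,2.2
males:65-79,2010-2012,458.7,1193.0,734.3,2.6
males:65-79,2013-2015,456.4,1087.0,630.6,2.4
males:65-79,2016-2018,411.6,998.7,587.1,2.4
males:80+,2007-2009,829.9,2413.0,1583.1,2.9
males:80+,2010-2012,798.6,2589.0,1790.4,3.2
males:80+,2013-2015,693.1,2425.0,1731.9,3.5
males:80+,2016-2018,745.8,2357.0,1611.2,3.2
females,2007-2009,89.6,234.3,144.7,2.6
females,2010-2012,85.5,262.5,177.0,3.1
females,2013-2015,80.8,248.8,168.0,3.1
females,2016-2018,75.8,221.3,145.5,2.9
females:35-49,2007-2009,6.3,17.9,11.6,2.8
females:35-49,2010-2012,6.0,22.1,16.1,3.7
females:35-49,2013-2015,5.8,27.2,21.4,4.7
females:35-49,2016-2018,5.8,19.9,14.1,3.4
females:50-64,2007-2009,37.4,134.4,97.0,3.6
females:50-64,2010-2012,38.9,153.3,114.4,3.9
females:50-64,2013-2015,37.2,147.7,110.5,4.0
females:50-64,2016-2018,41.3,131.1,89.8,3.2
females:65-79,2007-2009,312.1,830.4,518.3,2.7
females:65-79,2010-2012,316.3,932.4,616.1,2.9
females:65-79,2013-2015,291.6,855.3,563.7,2.9
females:65-79,2016-2018,231.0,721.3,490.3,3.1
females:80+,2007-2009,707.9,2638.0,1930.1,3.7
females:80+,2010-2012,723.4,3042.0,2318.6,4.2
females:80+,2013-2015,705.5,2655.0,1949.5,3.8
females:80+,2016-2018,679.8,2430.0,1750.2,3.6
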